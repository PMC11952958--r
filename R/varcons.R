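# ---------------------------------------------------------------------------
# Per-residue track handling (conservation grades, RNA-binding probabilities,
# variant positions) and the domain-level missense depletion statistic
# Vd/Vp: domain variant density over whole-protein variant density.
# ---------------------------------------------------------------------------

#' Construct a per-residue track
#'
#' @param protein protein label
#' @param values numeric vector, one value per residue (NA = missing)
#' @param semantics free-text tag, e.g. `"consurf_grade"`, `"rna_binding_prob"`
#' @return object of class `ResidueTrack`
#' @export
residue_track <- function(protein, values, semantics = "score") {
  if (length(values) == 0) stop("track must have positive length")
  structure(list(protein = protein, values = as.numeric(values),
                 length = length(values), semantics = semantics),
            class = "ResidueTrack")
}

#' Construct a variant set
#'
#' @param protein protein label
#' @param position residue positions (1-based)
#' @param change variant descriptors (e.g. `"R100Q"`); defaults to
#'   position-only descriptors
#' @param flags per-variant character vector (or comma-separated string) of
#'   flags, e.g. `"pathogenic"`, `"clinvar"`
#' @param source provenance label
#' @param protein_length declared protein length (positions validated against
#'   it when given)
#' @return object of class `VariantSet`: a data.frame with attributes
#' @export
variant_set <- function(protein, position, change = NULL, flags = NULL,
                        source = "synthetic", protein_length = NULL) {
  position <- as.integer(position)
  if (any(position < 1)) stop("variant positions must be >= 1")
  if (!is.null(protein_length) && any(position > protein_length))
    stop("variant position beyond protein length ", protein_length)
  n <- length(position)
  if (is.null(change))
    change <- if (n > 0) paste0("p", position) else character(0)
  if (is.null(flags)) flags <- rep("", n)
  if (length(flags) != n) flags <- rep_len(flags, n)
  out <- data.frame(position = position, change = as.character(change),
                    flags = as.character(flags),
                    source = rep_len(source, n),
                    stringsAsFactors = FALSE)
  attr(out, "protein") <- protein
  attr(out, "protein_length") <- protein_length
  class(out) <- c("VariantSet", "data.frame")
  out
}

#' Construct a domain annotation
#'
#' Named residue intervals, 1-based inclusive.
#' @param label domain labels (unique)
#' @param start,end interval bounds
#' @param protein_length optional length for validation
#' @return data.frame of class `DomainAnnotation`
#' @export
domain_annotation <- function(label, start, end, protein_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1) || any(end < start))
    stop("need 1 <= start <= end for every domain")
  if (!is.null(protein_length) && any(end > protein_length))
    stop("domain end beyond protein length")
  if (anyDuplicated(label)) stop("domain labels must be unique")
  out <- data.frame(label = as.character(label), start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("DomainAnnotation", "data.frame")
  out
}

#' Filter variants by exclusion flags
#'
#' Removes variants carrying any flag in the exclusion set (e.g. likely
#' pathogenic and ClinVar-reported variants before depletion analysis).
#' Applying the filter twice is a no-op.
#'
#' @param variants VariantSet
#' @param exclude flags to remove (default `c("pathogenic", "clinvar")`)
#' @return filtered VariantSet; attribute `removed` counts removals per flag
#' @export
filter_variants <- function(variants, exclude = c("pathogenic", "clinvar")) {
  fl <- strsplit(variants$flags, "[,;]\\s*")
  hit <- vapply(fl, function(f) any(f %in% exclude), logical(1))
  removed <- vapply(exclude, function(e)
    sum(vapply(fl, function(f) e %in% f, logical(1)) & hit), integer(1))
  out <- variants[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "protein") <- attr(variants, "protein")
  attr(out, "protein_length") <- attr(variants, "protein_length")
  class(out) <- class(variants)
  attr(out, "removed") <- removed
  out
}

#' Domain missense depletion ratio Vd/Vp
#'
#' `Vd` is the density of unique variants inside the domain (count / domain
#' length); `Vp` is the whole-protein density (count / protein length). Values
#' below 1 indicate localized depletion of missense variation within the
#' domain. The counting unit is a unique (position, change) pair by default;
#' `unit = "position"` counts unique positions instead.
#'
#' @param variants VariantSet (filter first with [filter_variants()])
#' @param domain either a numeric `c(start, end)` or one row of a
#'   [domain_annotation()]
#' @param protein_length protein length in residues
#' @param unit `"change"` (default) or `"position"`
#' @return list with `ratio`, `v_d`, `v_p`, `n_domain`, `n_total`, `status`
#'   (`"ok"`, or `"undefined"` when the protein carries no variants)
#' @export
depletion_ratio <- function(variants, domain, protein_length,
                            unit = c("change", "position")) {
  unit <- match.arg(unit)
  if (is.data.frame(domain)) {
    start <- domain$start[1]; end <- domain$end[1]
  } else {
    start <- domain[1]; end <- domain[2]
  }
  if (start < 1 || end > protein_length || end < start)
    stop("domain must lie within 1..protein_length")
  key <- if (unit == "change")
    paste(variants$position, variants$change) else variants$position
  uniq <- !duplicated(key)
  pos <- variants$position[uniq]
  n_total <- sum(uniq)
  if (n_total == 0)
    return(list(ratio = NA_real_, v_d = NA_real_, v_p = NA_real_,
                n_domain = 0L, n_total = 0L, status = "undefined"))
  n_dom <- sum(pos >= start & pos <= end)
  v_d <- n_dom / (end - start + 1)
  v_p <- n_total / protein_length
  list(ratio = v_d / v_p, v_d = v_d, v_p = v_p,
       n_domain = n_dom, n_total = n_total, status = "ok")
}

#' Combine residue tracks, variants and domains into one table
#'
#' One row per residue with every track value, the per-residue variant count,
#' and domain membership; the standard export for plotting.
#'
#' @param tracks named list of [residue_track()] objects (may be empty)
#' @param variants VariantSet or NULL
#' @param domains DomainAnnotation or NULL
#' @param protein_length length; inferred from the first track if missing
#' @return data.frame with `position`, one column per track, `variant_count`,
#'   `domain`
#' @export
combine_tracks <- function(tracks = list(), variants = NULL, domains = NULL,
                           protein_length = NULL) {
  if (is.null(protein_length)) {
    if (length(tracks) == 0)
      stop("protein_length required when no tracks are given")
    protein_length <- tracks[[1]]$length
  }
  for (nm in names(tracks))
    if (tracks[[nm]]$length != protein_length)
      stop("track '", nm, "' length ", tracks[[nm]]$length,
           " does not match protein length ", protein_length)
  out <- data.frame(position = seq_len(protein_length))
  for (nm in names(tracks)) out[[nm]] <- tracks[[nm]]$values
  vc <- integer(protein_length)
  if (!is.null(variants) && nrow(variants) > 0) {
    if (max(variants$position) > protein_length)
      stop("variant set exceeds protein length (source: ",
           attr(variants, "protein"), ")")
    tb <- table(variants$position)
    vc[as.integer(names(tb))] <- as.integer(tb)
  }
  out$variant_count <- vc
  dom <- rep(NA_character_, protein_length)
  if (!is.null(domains)) {
    for (i in seq_len(nrow(domains)))
      dom[domains$start[i]:domains$end[i]] <- domains$label[i]
  }
  out$domain <- dom
  out
}

#' Read a 2-column position/value track
#' @param path TSV with columns position, value ('#' comments allowed)
#' @param protein protein label
#' @param protein_length declared length (positions beyond it are an error)
#' @param semantics semantics tag
#' @return ResidueTrack (missing positions NA)
#' @export
read_track <- function(path, protein, protein_length, semantics = "score") {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  vals <- rep(NA_real_, protein_length)
  pos <- as.integer(tab[[1]])
  if (any(pos < 1 | pos > protein_length))
    stop("track positions outside 1..", protein_length, " in ", path)
  vals[pos] <- as.numeric(tab[[2]])
  residue_track(protein, vals, semantics)
}
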