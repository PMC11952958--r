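# ---------------------------------------------------------------------------
# Quantitative cross-linking MS: loading Skyline-style feature tables,
# fold-change classification between two conditions, mapping features onto
# structural models (with crystallographic symmetry expansion) against the
# EDC Calpha-Calpha distance contract, and competitive scoring of assembly
# hypotheses.
# ---------------------------------------------------------------------------

#' Define a cross-link table schema
#'
#' Maps table columns to the fields of a cross-linking feature: the two linked
#' sites (protein label + residue number) and the replicate intensity columns
#' of each condition.
#'
#' @param protein_a,residue_a,protein_b,residue_b column names for the sites
#' @param conditions named list: condition label -> character vector of
#'   intensity column names (one per replicate)
#' @param charge,modification optional column names used to distinguish
#'   features
#' @return schema list
#' @export
crosslink_schema <- function(protein_a, residue_a, protein_b, residue_b,
                             conditions, charge = NULL, modification = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  list(protein_a = protein_a, residue_a = residue_a,
       protein_b = protein_b, residue_b = residue_b,
       conditions = conditions, charge = charge, modification = modification)
}

#' Load cross-linking features from a CSV/TSV table
#'
#' One feature per row; duplicate (site A, site B, charge, modification) rows
#' are merged by summing their areas, with a warning. Rows whose residue
#' fields do not parse as positive integers are collected as row-level errors
#' (attribute `errors`) rather than aborting the load.
#'
#' @param path CSV (default) or TSV file
#' @param schema a [crosslink_schema()]
#' @param sep field separator; `","` or `"\t"`
#' @return data.frame of features: `protein_a`, `residue_a`, `protein_b`,
#'   `residue_b`, `charge`, `modification`, plus one column per intensity
#'   column; attribute `schema` retained, attribute `errors` lists skipped
#'   rows.
#' @export
load_crosslinks <- function(path, schema, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  icols <- unlist(schema$conditions, use.names = FALSE)
  need <- c(schema$protein_a, schema$residue_a, schema$protein_b,
            schema$residue_b, icols)
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("table lacks column(s): ", paste(miss, collapse = ", "))
  res_a <- suppressWarnings(as.integer(tab[[schema$residue_a]]))
  res_b <- suppressWarnings(as.integer(tab[[schema$residue_b]]))
  bad <- which(is.na(res_a) | res_a <= 0 | is.na(res_b) | res_b <= 0)
  feats <- data.frame(
    protein_a = as.character(tab[[schema$protein_a]]),
    residue_a = res_a,
    protein_b = as.character(tab[[schema$protein_b]]),
    residue_b = res_b,
    charge = if (!is.null(schema$charge)) tab[[schema$charge]] else NA,
    modification = if (!is.null(schema$modification))
      tab[[schema$modification]] else NA,
    stringsAsFactors = FALSE)
  for (cc in icols) feats[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
  errors <- if (length(bad) > 0)
    data.frame(row = bad, reason = "unparseable residue number") else NULL
  if (length(bad) > 0) feats <- feats[-bad, , drop = FALSE]
  key <- paste(feats$protein_a, feats$residue_a, feats$protein_b,
               feats$residue_b, feats$charge, feats$modification)
  if (anyDuplicated(key)) {
    warning("duplicate features merged by summing areas")
    agg <- stats::aggregate(feats[icols], by = list(key = key),
                            FUN = function(x)
                              if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
    first <- feats[!duplicated(key), setdiff(names(feats), icols),
                   drop = FALSE]
    first <- first[match(agg$key, key[!duplicated(key)]), , drop = FALSE]
    feats <- cbind(first, agg[icols])
    rownames(feats) <- NULL
  }
  attr(feats, "schema") <- schema
  attr(feats, "errors") <- errors
  feats
}

#' Classify cross-link features by fold change between two conditions
#'
#' Fold change is the ratio of the means of non-missing replicate areas,
#' `FC = mean(B) / mean(A)`. A feature is `B_enriched` when `FC >=
#' fold_threshold`, `A_enriched` when `FC <= 1/fold_threshold`, otherwise
#' `common`. Features detected in only one condition (>= `min_replicates`
#' non-missing areas there, none in the other) are assigned to that
#' condition's enriched class with `FC = Inf` or `0` and flagged
#' `one_condition_only`; features below the detection rule are
#' `unquantified`. Missing values are never imputed. A Welch t statistic per
#' feature is reported as a labelled extension (the classification itself is
#' the pure fold-change rule).
#'
#' @param features feature table from [load_crosslinks()] (or the same shape)
#' @param conditions character(2): condition labels `c(A, B)`; must match the
#'   schema's condition names
#' @param fold_threshold enrichment threshold (default 2)
#' @param min_replicates detections required to call a one-condition feature
#'   enriched (default 2)
#' @return the feature table with added columns `mean_A`, `mean_B`, `fc`,
#'   `category` (factor: `A_enriched`, `B_enriched`, `common`,
#'   `unquantified`), `one_condition_only`, `t_stat`; attribute `threshold`.
#' @export
classify_quant <- function(features, conditions, fold_threshold = 2,
                           min_replicates = 2) {
  schema <- attr(features, "schema")
  if (is.null(schema)) stop("features must carry a schema attribute")
  if (length(conditions) != 2)
    stop("exactly two condition labels required")
  if (!all(conditions %in% names(schema$conditions)))
    stop("unknown condition label(s): ",
         paste(setdiff(conditions, names(schema$conditions)), collapse = ", "))
  colsA <- schema$conditions[[conditions[1]]]
  colsB <- schema$conditions[[conditions[2]]]
  A <- as.matrix(features[colsA])
  B <- as.matrix(features[colsB])
  nA <- rowSums(!is.na(A))
  nB <- rowSums(!is.na(B))
  mA <- ifelse(nA > 0, rowMeans(A, na.rm = TRUE), NA)
  mB <- ifelse(nB > 0, rowMeans(B, na.rm = TRUE), NA)
  fc <- mB / mA
  category <- rep("unquantified", nrow(features))
  one_only <- rep(FALSE, nrow(features))
  both <- nA > 0 & nB > 0
  category[both & fc >= fold_threshold] <- "B_enriched"
  category[both & fc <= 1 / fold_threshold] <- "A_enriched"
  category[both & fc < fold_threshold & fc > 1 / fold_threshold] <- "common"
  onlyB <- nA == 0 & nB >= min_replicates
  onlyA <- nB == 0 & nA >= min_replicates
  category[onlyB] <- "B_enriched"; fc[onlyB] <- Inf; one_only[onlyB] <- TRUE
  category[onlyA] <- "A_enriched"; fc[onlyA] <- 0; one_only[onlyA] <- TRUE
  tstat <- rep(NA_real_, nrow(features))
  can_t <- nA >= 2 & nB >= 2
  if (any(can_t)) {
    vA <- apply(A, 1, stats::var, na.rm = TRUE)
    vB <- apply(B, 1, stats::var, na.rm = TRUE)
    tstat[can_t] <- (mB[can_t] - mA[can_t]) /
      sqrt(vA[can_t] / nA[can_t] + vB[can_t] / nB[can_t])
  }
  out <- features
  out$mean_A <- mA; out$mean_B <- mB; out$fc <- fc
  out$category <- factor(category, levels = c("A_enriched", "B_enriched",
                                              "common", "unquantified"))
  out$one_condition_only <- one_only
  out$t_stat <- tstat
  attr(out, "schema") <- schema
  attr(out, "threshold") <- fold_threshold
  attr(out, "conditions") <- conditions
  out
}

# --- distance mapping -------------------------------------------------------

anchor_or_na <- function(model, chain, resno) {
  tryCatch(residue_anchor(model, chain, resno), error = function(e) NULL)
}

#' Candidate anchor points for a site across model copies
#'
#' Internal helper: returns a matrix of anchor coordinates for (protein,
#' residue) over all chains the protein maps to, over all models in a list,
#' and (optionally) over symmetry mates generated from each model's cell.
#' @noRd
site_anchors <- function(models, protein, resno, chain_map, use_symmetry,
                         lattice_range = 2) {
  pts <- NULL
  tags <- character(0)
  chains <- chain_map[[protein]]
  if (is.null(chains)) return(list(pts = NULL, tags = tags))
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    for (ch in chains) {
      xyz <- anchor_or_na(model, ch, resno)
      if (is.null(xyz)) next
      pts <- rbind(pts, as.numeric(xyz))
      tags <- c(tags, sprintf("%s:%s:identity", model$model_id, ch))
      if (use_symmetry && !is.null(model$cell) && !is.null(model$symops)) {
        M <- cell_matrix(model$cell)
        Minv <- solve(M)
        f <- as.numeric(Minv %*% xyz)
        shifts <- as.matrix(expand.grid(-lattice_range:lattice_range,
                                        -lattice_range:lattice_range,
                                        -lattice_range:lattice_range))
        for (k in seq_along(model$symops)) {
          op <- model$symops[[k]]
          f1 <- as.numeric(op$R %*% f) + op$t
          xs <- t(M %*% (t(shifts) + f1))
          pts <- rbind(pts, xs)
          tags <- c(tags, sprintf("%s:%s:op%d_%d.%d.%d", model$model_id, ch,
                                  k, shifts[, 1], shifts[, 2], shifts[, 3]))
        }
      }
    }
  }
  list(pts = pts, tags = tags)
}

#' Map cross-link features onto structural models
#'
#' For each feature, finds the minimal Calpha-Calpha distance between its two
#' sites over all supplied model copies, all chains its proteins map to, and
#' (when enabled) all crystallographic symmetry mates within the lattice
#' search block. Homodimeric ambiguity (a protein present as several chains)
#' is resolved by the minimum over chain-pair assignments. Site A is held in
#' the identity copy; site B is enumerated over operators and lattice shifts,
#' which covers all relative placements of a space group.
#'
#' @param features feature table (as from [load_crosslinks()])
#' @param models a StructureModel or list of StructureModels
#' @param chain_map named list: protein label -> character vector of chain ids
#' @param use_symmetry expand over crystal symmetry when cell/operators are
#'   present (default TRUE)
#' @param cutoff satisfaction cutoff in Angstrom (default 24, the EDC
#'   Calpha-Calpha allowance)
#' @param lattice_range lattice translation half-width (default 2)
#' @return data.frame: one row per feature with `distance`, `copy`
#'   (description of the achieving copy), `satisfied`, `status`
#' @export
map_distance <- function(features, models, chain_map, use_symmetry = TRUE,
                         cutoff = 24, lattice_range = 2) {
  if (inherits(models, "StructureModel")) models <- list(models)
  n <- nrow(features)
  out <- data.frame(distance = rep(NA_real_, n), copy = NA_character_,
                    satisfied = NA, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pa <- features$protein_a[i]; ra <- features$residue_a[i]
    pb <- features$protein_b[i]; rb <- features$residue_b[i]
    sa <- site_anchors(models, pa, ra, chain_map, use_symmetry = FALSE)
    sb <- site_anchors(models, pb, rb, chain_map, use_symmetry, lattice_range)
    if (is.null(sa$pts) || is.null(sb$pts)) {
      out$status[i] <- sprintf("unresolvable site %s:%s or %s:%s",
                               pa, ra, pb, rb)
      next
    }
    # also allow A over symmetry when B is fixed, covered by symmetric search:
    # relative transforms form a group, so fixing A in the identity suffices.
    d2 <- outer(rowSums(sa$pts^2), rowSums(sb$pts^2), "+") -
      2 * sa$pts %*% t(sb$pts)
    d2[d2 < 0] <- 0
    j <- arrayInd(which.min(d2), dim(d2))
    out$distance[i] <- sqrt(d2[j])
    out$copy[i] <- paste(sa$tags[j[1]], sb$tags[j[2]], sep = " | ")
    out$satisfied[i] <- out$distance[i] <= cutoff
  }
  attr(out, "cutoff") <- cutoff
  out
}

#' Write a distance report as a restraint file
#'
#' Plain text: `proteinA resA proteinB resB distance satisfied`, one feature
#' per line.
#' @param features feature table
#' @param report output of [map_distance()] for those features
#' @param path output file
#' @export
write_restraints <- function(features, report, path) {
  df <- data.frame(features$protein_a, features$residue_a,
                   features$protein_b, features$residue_b,
                   round(report$distance, 2), report$satisfied)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Score competing assembly hypotheses against cross-link features
#'
#' Each named assembly (a StructureModel, a list of models, or a
#' `list(model =, chain_map =)` entry) is scored by the number and fraction of
#' features satisfied at the cutoff; assemblies are ranked by satisfied
#' fraction, ties broken by the mean distance of violated links (smaller is
#' better).
#'
#' @param features feature table
#' @param assemblies named list of assemblies
#' @param chain_map default chain map used when an assembly does not carry one
#' @param cutoff Angstrom (default 24)
#' @param use_symmetry passed to [map_distance()] (default FALSE: assemblies
#'   are usually explicit multi-copy models)
#' @return list with `table` (one row per assembly: satisfied, total,
#'   fraction, mean_violated_distance, rank) and `reports` (per-assembly
#'   distance reports)
#' @export
evaluate_assemblies <- function(features, assemblies, chain_map = NULL,
                                cutoff = 24, use_symmetry = FALSE) {
  if (length(assemblies) < 2)
    stop("need at least 2 assemblies to compare")
  if (is.null(names(assemblies)) || any(!nzchar(names(assemblies))))
    stop("assemblies must be named")
  reports <- list()
  rows <- list()
  for (nm in names(assemblies)) {
    a <- assemblies[[nm]]
    cm <- chain_map
    if (is.list(a) && !inherits(a, "StructureModel") &&
        !is.null(a$model)) {
      if (!is.null(a$chain_map)) cm <- a$chain_map
      a <- a$model
    }
    if (is.null(cm)) stop("no chain map for assembly ", nm)
    rep_i <- map_distance(features, a, cm, use_symmetry = use_symmetry,
                          cutoff = cutoff)
    reports[[nm]] <- rep_i
    ok <- rep_i$satisfied
    viol <- rep_i$distance[!is.na(ok) & !ok]
    rows[[nm]] <- data.frame(
      assembly = nm,
      satisfied = sum(ok, na.rm = TRUE),
      total = sum(!is.na(ok)),
      fraction = sum(ok, na.rm = TRUE) / max(1, sum(!is.na(ok))),
      mean_violated_distance = if (length(viol) > 0) mean(viol) else 0,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$fraction, tab$mean_violated_distance)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  rownames(tab) <- NULL
  list(table = tab, reports = reports)
}
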