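# ---------------------------------------------------------------------------
# Stoichiometry and oligomerization: component masses, mass-photometry peak
# fitting, (protein, RNA) composition assignment, steric footprint intervals
# on duplex RNA, lateral oligomer assembly with clash checks, and
# bead-on-string particle statistics.
# ---------------------------------------------------------------------------

# Average residue masses (Da), standard amino-acid residues in a chain
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153
RNA_NT_RESIDUE_MASS <- 320.5  # average Da per nucleotide residue in a duplex

#' Mass of a protein or dsRNA component
#'
#' Protein mass is the sum of average residue masses plus one water (a free
#' amino acid is residue + water: glycine = 75.07 Da). dsRNA mass defaults to
#' `2 * bp * 320.5` Da per nucleotide residue, an average-composition
#' approximation; pass `rna_nt_mass` for a sequence-exact value and
#' `end_correction` (Da per duplex) for terminal groups.
#'
#' @param sequence one-letter protein sequence (string or vector), or NULL
#' @param rna_bp duplex length in base pairs, or NULL
#' @param tag_mass extra mass in Da (purification tags etc.)
#' @param rna_nt_mass average nucleotide residue mass (Da, default 320.5)
#' @param end_correction additive correction per duplex in Da (default 0)
#' @return mass in kDa, with attribute `constants`
#' @export
component_mass <- function(sequence = NULL, rna_bp = NULL, tag_mass = 0,
                           rna_nt_mass = RNA_NT_RESIDUE_MASS,
                           end_correction = 0) {
  mass <- tag_mass
  if (!is.null(sequence)) {
    aa <- strsplit(toupper(paste(sequence, collapse = "")), "")[[1]]
    bad <- setdiff(unique(aa), names(AA_RESIDUE_MASS))
    if (length(bad) > 0)
      stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
    mass <- mass + sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
  }
  if (!is.null(rna_bp)) {
    if (rna_bp <= 0) stop("rna_bp must be positive")
    mass <- mass + 2 * rna_bp * rna_nt_mass + end_correction
  }
  if (is.null(sequence) && is.null(rna_bp) && tag_mass == 0)
    stop("nothing to weigh")
  structure(mass / 1000,
            constants = list(water = WATER_MASS, rna_nt = rna_nt_mass,
                             end_correction = end_correction))
}

#' Fit Gaussian peaks to mass-photometry events
#'
#' One-dimensional Gaussian mixture over particle-mass events
#' (`mclust::Mclust`, unequal variances). With `n_peaks = "auto"` the
#' component count is selected by BIC over 1..`max_components` and at least 50
#' events are required.
#'
#' @param events numeric vector of event masses (kDa)
#' @param n_peaks integer, or `"auto"`
#' @param max_components upper bound for auto mode (default 6)
#' @importFrom mclust Mclust mclustBIC
#' @return data.frame of class `MassPeaks`: `mass`, `width` (sd), `abundance`
#'   (mixing fraction), sorted by mass
#' @export
fit_mass_peaks <- function(events, n_peaks = "auto", max_components = 6) {
  if (length(events) == 0) stop("no mass events supplied")
  if (identical(n_peaks, "auto")) {
    if (length(events) < 50)
      stop("auto peak detection requires >= 50 events (got ",
           length(events), ")")
    G <- 1:max_components
  } else {
    G <- as.integer(n_peaks)
  }
  fit <- Mclust(events, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    fit <- Mclust(events, G = G, modelNames = "E", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit did not converge (n = ",
                         length(events), ", G = ", paste(G, collapse = ","),
                         ")")
  mu <- as.numeric(fit$parameters$mean)
  sd_ <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd_) == 1) sd_ <- rep(sd_, length(mu))
  pro <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  out <- data.frame(mass = mu[ord], width = sd_[ord], abundance = pro[ord])
  class(out) <- c("MassPeaks", "data.frame")
  out
}

#' Assign (protein, RNA) stoichiometries to mass peaks
#'
#' Enumerates all compositions `(n_protein <= max_copies, n_rna <= max_copies)`
#' except (0, 0); a peak is assigned the composition with the smallest
#' absolute residual `|n_p m_p + n_r m_r - mass|` within `tolerance`, ties
#' broken by the smaller total copy number, then by fewer proteins.
#'
#' @param peaks numeric masses (kDa) or a `MassPeaks` table
#' @param m_protein,m_rna component masses (kDa)
#' @param max_copies enumeration bound per component (default 10)
#' @param tolerance acceptance tolerance (kDa)
#' @return data.frame: `peak`, `n_protein`, `n_rna`, `predicted`, `residual`,
#'   `assigned`
#' @export
assign_stoichiometry <- function(peaks, m_protein, m_rna, max_copies = 10,
                                 tolerance = 10) {
  if (m_protein <= 0 || m_rna <= 0) stop("component masses must be positive")
  masses <- if (is.data.frame(peaks)) peaks$mass else as.numeric(peaks)
  grid <- expand.grid(n_protein = 0:max_copies, n_rna = 0:max_copies)
  grid <- grid[grid$n_protein + grid$n_rna > 0, , drop = FALSE]
  grid$predicted <- grid$n_protein * m_protein + grid$n_rna * m_rna
  rows <- lapply(masses, function(m) {
    resid <- abs(grid$predicted - m)
    ok <- resid <= tolerance
    if (!any(ok))
      return(data.frame(peak = m, n_protein = NA_integer_,
                        n_rna = NA_integer_, predicted = NA_real_,
                        residual = NA_real_, assigned = FALSE))
    cand <- grid[ok, , drop = FALSE]
    cand$residual <- resid[ok]
    ord <- order(cand$residual, cand$n_protein + cand$n_rna, cand$n_protein)
    b <- cand[ord[1], ]
    data.frame(peak = m, n_protein = b$n_protein, n_rna = b$n_rna,
               predicted = b$predicted, residual = b$residual,
               assigned = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steric footprint interval from maximal occupancy observations
#'
#' Each observation — a duplex of `length_bp` base pairs accommodating at most
#' `max_pairs` sandwiching pairs of complexes — constrains the per-pair
#' footprint `f` to the half-open interval `(L/(k+1), L/k]`: `k` pairs fit
#' (`k f <= L`) but `k + 1` do not (`(k+1) f > L`). The result is the
#' intersection over observations; inconsistent observations yield an empty
#' interval with diagnostics, not an error.
#'
#' @param observations data.frame with columns `length_bp`, `max_pairs` (or a
#'   list of `c(L, k)` pairs)
#' @return list with `lower` (exclusive), `upper` (inclusive), `empty`,
#'   `per_observation`
#' @export
footprint_interval <- function(observations) {
  if (!is.data.frame(observations))
    observations <- do.call(rbind, lapply(observations, function(x)
      data.frame(length_bp = x[1], max_pairs = x[2])))
  if (nrow(observations) == 0) stop("need at least one observation")
  if (any(observations$max_pairs < 1)) stop("max_pairs must be >= 1")
  per <- data.frame(length_bp = observations$length_bp,
                    max_pairs = observations$max_pairs,
                    lower = observations$length_bp /
                      (observations$max_pairs + 1),
                    upper = observations$length_bp / observations$max_pairs)
  lower <- max(per$lower)
  upper <- min(per$upper)
  list(lower = lower, upper = upper, empty = upper <= lower,
       per_observation = per)
}

#' Convert complex counts to sandwiching-pair counts
#'
#' Complexes bind duplex RNA as sandwiching pairs (two complexes per duplex
#' cross-section); an odd count still occupies a full cross-section.
#' @param n_complexes observed complexes per duplex
#' @return pair count (ceiling of n/2)
#' @export
complexes_to_pairs <- function(n_complexes) ceiling(n_complexes / 2)

#' A-form helical rise (Angstrom per base pair)
#'
#' Used when converting footprints between base pairs and Angstrom.
#' @export
A_FORM_RISE <- 2.81

#' Build a lateral oligomer from a repeating unit
#'
#' Places `n` copies of the unit, each displaced by a rigid step: either a
#' translation of `rise` Angstrom along `axis`, or an explicit
#' `transform = list(R, t)` applied cumulatively. Copies get chain labels
#' `<chain>.<copy>`. The clash report counts inter-copy heavy-atom pairs
#' closer than `clash_cutoff` (default 2.5 Angstrom) and gives the minimal
#' inter-copy distance; an identity step sets the clash flag.
#'
#' @param unit StructureModel
#' @param n number of copies (>= 2)
#' @param rise translation step (Angstrom), used when `transform` is NULL
#' @param axis unit direction of the rise (default x)
#' @param transform optional `list(R = 3x3, t = length-3)` rigid step
#' @param clash_cutoff Angstrom (default 2.5)
#' @return list with `assembly` (merged StructureModel), `copies` (list of
#'   models), `clash_count`, `min_intercopy_distance`, `clash_flag`
#' @export
build_lateral_oligomer <- function(unit, n = 2, rise = NULL,
                                   axis = c(1, 0, 0), transform = NULL,
                                   clash_cutoff = 2.5) {
  if (n < 2) stop("need n >= 2 copies")
  if (is.null(transform)) {
    if (is.null(rise)) stop("give either rise or transform")
    axis <- axis / sqrt(sum(axis^2))
    transform <- list(R = diag(3), t = rise * axis)
  }
  if (abs(det(transform$R)) < 1e-12) stop("transform must be invertible")
  copies <- vector("list", n)
  R_acc <- diag(3); t_acc <- c(0, 0, 0)
  for (k in seq_len(n)) {
    copies[[k]] <- transform_model(unit, R_acc, t_acc,
                                   model_id = paste0(unit$model_id, "_c", k))
    at <- copies[[k]]$atoms
    at$chain <- paste0(at$chain, ".", k)
    copies[[k]]$atoms <- at
    t_acc <- as.numeric(transform$R %*% t_acc) + transform$t
    R_acc <- transform$R %*% R_acc
  }
  merged <- structure_model(do.call(rbind, lapply(copies, `[[`, "atoms")),
                            model_id = paste0(unit$model_id, "_x", n))
  # inter-copy clash scan over heavy atoms
  clash <- 0L
  mind <- Inf
  heavy <- lapply(copies, function(m)
    as.matrix(m$atoms[m$atoms$elesy != "H", c("x", "y", "z")]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- heavy[[i]]; b <- heavy[[j]]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    d2[d2 < 0] <- 0
    clash <- clash + sum(d2 < clash_cutoff^2)
    mind <- min(mind, sqrt(min(d2)))
  }
  list(assembly = merged, copies = copies, clash_count = clash,
       min_intercopy_distance = mind, clash_flag = clash > 0)
}

#' Bead-on-string particle statistics
#'
#' Pools consecutive-centre distances within each string (interparticle
#' spacing) and summarizes spacing, bead length and bead width. Units are
#' taken from the measurement set's declaration (`"angstrom"` or `"nm"`,
#' converted to Angstrom).
#'
#' @param measurements data.frame with columns `string_id`, `bead_index`,
#'   `x`, `y`, `length`, `width` and attribute `units` (or a `units` argument)
#' @param units overrides the attribute; required if neither is set
#' @return list of summaries: `spacing`, `length`, `width`, each with
#'   mean/median/sd/n
#' @export
bead_string_stats <- function(measurements, units = NULL) {
  u <- units %||% attr(measurements, "units")
  if (is.null(u)) stop("units not declared (angstrom or nm)")
  if (!u %in% c("angstrom", "nm")) stop("unknown unit: ", u)
  fac <- if (u == "nm") 10 else 1
  spac <- unlist(lapply(split(measurements, measurements$string_id),
                        function(s) {
    s <- s[order(s$bead_index), , drop = FALSE]
    if (nrow(s) < 2) return(numeric(0))
    sqrt(diff(s$x)^2 + diff(s$y)^2) * fac
  }), use.names = FALSE)
  summ <- function(x) list(mean = if (length(x)) mean(x) else NA_real_,
                           median = if (length(x)) stats::median(x) else NA_real_,
                           sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                           n = length(x))
  list(spacing = summ(spac),
       length = summ(measurements$length * fac),
       width = summ(measurements$width * fac))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
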