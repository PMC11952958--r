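# ---------------------------------------------------------------------------
# Solution SAXS analysis: SEC frame reduction, Guinier fitting, regularized
# indirect Fourier transform (P(r), Dmax), dimensionless Kratky transform,
# volume-of-correlation molecular weight, Debye curves from coordinates, and
# sparse multi-state fitting.
# ---------------------------------------------------------------------------

#' Construct a ScatteringCurve
#'
#' @param q momentum transfer, 1/Angstrom, strictly increasing and positive
#' @param I intensity (arbitrary units)
#' @param sigma pointwise uncertainty, same units as I
#' @param label sample label
#' @return object of class `ScatteringCurve` (a data.frame with attributes)
#' @export
scattering_curve <- function(q, I, sigma = NULL, label = "") {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I lengths differ")
  if (any(q <= 0)) stop("q must be positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  if (length(sigma) == 1) sigma <- rep(sigma, length(q))
  if (length(sigma) != length(q)) stop("sigma length mismatch")
  if (any(!is.na(sigma) & sigma <= 0)) stop("sigma must be positive where given")
  # heuristic unit check: protein SAXS q in 1/A rarely exceeds ~1
  if (max(q) > 2)
    warning("qmax > 2: q may be in 1/nm; divide by 10 to convert to 1/Angstrom")
  out <- data.frame(q = q, I = I, sigma = sigma)
  attr(out, "label") <- label
  class(out) <- c("ScatteringCurve", "data.frame")
  out
}

#' Read a 3-column SAXS curve (q, I, sigma)
#'
#' Whitespace-delimited text; `#` comments and non-numeric header lines are
#' skipped (ATSAS-style headers tolerated).
#' @param path file path
#' @param label sample label (default: file name)
#' @return ScatteringCurve
#' @export
read_saxs_curve <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  numeric_row <- vapply(fields, function(f)
    length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f[1:2]))), logical(1))
  fields <- fields[numeric_row]
  if (length(fields) == 0) stop("no numeric data rows in ", path)
  q <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  I <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  s <- vapply(fields, function(f)
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else NA_real_,
    numeric(1))
  scattering_curve(q, I, s, label = label)
}

#' Write a SAXS curve as 3-column text
#' @param curve ScatteringCurve
#' @param path output path
#' @export
write_saxs_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# q(1/A)  I  sigma  [", attr(curve, "label"), "]"), con)
  utils::write.table(format(curve[, c("q", "I", "sigma")], digits = 10),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Reduce SEC-SAXS frames: buffer subtraction and elution profile
#'
#' Averages sample frames and buffer frames on a common q grid and returns
#' mean(sample) - mean(buffer), with sigma propagated in quadrature and
#' divided by the frame counts. The per-frame total intensity (the elution
#' profile) is attached for peak inspection.
#'
#' @param frames list of ScatteringCurve, all on the same q grid
#' @param buffer_ids indices of buffer frames
#' @param sample_ids indices of sample frames (disjoint from buffer)
#' @return ScatteringCurve with attribute `elution` (data.frame frame/total)
#' @export
reduce_sec_frames <- function(frames, buffer_ids, sample_ids) {
  if (length(buffer_ids) == 0 || length(sample_ids) == 0)
    stop("buffer and sample frame sets must be non-empty")
  if (length(intersect(buffer_ids, sample_ids)) > 0)
    stop("buffer and sample frame sets overlap")
  q0 <- frames[[1]]$q
  for (f in frames)
    if (length(f$q) != length(q0) || any(abs(f$q - q0) > 1e-12))
      stop("frames are not on a common q grid (no silent interpolation)")
  msample <- rowMeans(sapply(frames[sample_ids], function(f) f$I))
  mbuffer <- rowMeans(sapply(frames[buffer_ids], function(f) f$I))
  vs <- rowSums(sapply(frames[sample_ids], function(f) f$sigma^2)) /
    length(sample_ids)^2
  vb <- rowSums(sapply(frames[buffer_ids], function(f) f$sigma^2)) /
    length(buffer_ids)^2
  out <- scattering_curve(q0, msample - mbuffer, sqrt(vs + vb),
                          label = "reduced")
  attr(out, "elution") <- data.frame(
    frame = seq_along(frames),
    total = vapply(frames, function(f) sum(f$I), numeric(1)))
  out
}

# --- Guinier ----------------------------------------------------------------

#' Guinier fit of the low-q region
#'
#' Weighted linear fit of ln I against q^2 on the largest low-q window
#' satisfying `qmax * Rg <= qRg_limit`, iterated to self-consistency.
#' `Rg = sqrt(-3 * slope)`, `I0 = exp(intercept)`. Weights are `(I/sigma)^2`
#' (the delta-method variance of ln I); unweighted when sigma is absent.
#'
#' @param curve ScatteringCurve
#' @param qRg_limit upper bound on qmax*Rg for the fitted window (default 1.3)
#' @param min_points minimum points in the window (default 5)
#' @return list with `Rg`, `I0`, `q_range`, `qRg_range`, `npts`,
#'   `residual_sd`, `status` (`"ok"` or `"failed"`)
#' @export
guinier_fit <- function(curve, qRg_limit = 1.3, min_points = 5) {
  ok <- curve$I > 0
  q <- curve$q[ok]; I <- curve$I[ok]; s <- curve$sigma[ok]
  if (length(q) < min_points)
    return(list(status = "failed", reason = "too few positive-I points"))
  w <- if (all(is.na(s))) rep(1, length(q)) else (I / s)^2
  fit_window <- function(n) {
    idx <- seq_len(n)
    fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2), weights = w[idx])
    co <- stats::coef(fit)
    list(slope = co[2], intercept = co[1], fit = fit)
  }
  n <- min(length(q), max(min_points, 10L))
  for (iter in 1:100) {
    f <- fit_window(n)
    if (!is.finite(f$slope) || f$slope >= 0)
      return(list(status = "failed",
                  reason = "non-negative Guinier slope (rising low-q)"))
    Rg <- sqrt(-3 * f$slope)
    n_new <- max(min_points, sum(q * Rg <= qRg_limit))
    n_new <- min(n_new, length(q))
    if (n_new == n) break
    n <- n_new
  }
  f <- fit_window(n)
  if (!is.finite(f$slope) || f$slope >= 0)
    return(list(status = "failed", reason = "non-negative Guinier slope"))
  Rg <- as.numeric(sqrt(-3 * f$slope))
  list(status = "ok",
       Rg = Rg,
       I0 = as.numeric(exp(f$intercept)),
       q_range = c(q[1], q[n]),
       qRg_range = c(q[1] * Rg, q[n] * Rg),
       npts = n,
       residual_sd = stats::sd(stats::residuals(f$fit)))
}

# --- indirect Fourier transform --------------------------------------------

#' Construct a PairDistribution
#' @param r uniform r grid from 0 to Dmax (Angstrom)
#' @param p p(r) values, non-negative
#' @param dmax maximum dimension (Angstrom)
#' @param alpha regularization weight used (NA for histograms)
#' @param chi2 back-computed reduced chi-square against the data (NA if n/a)
#' @param check_endpoints enforce p(0) = p(Dmax) = 0 (TRUE for IFT output)
#' @return object of class `PairDistribution`
#' @export
pair_distribution <- function(r, p, dmax, alpha = NA, chi2 = NA,
                              check_endpoints = TRUE) {
  if (any(p < -1e-9 * max(abs(p)))) stop("p(r) must be non-negative")
  p[p < 0] <- 0
  dr <- diff(r)
  if (max(abs(dr - dr[1])) > 1e-8 * dr[1]) stop("r grid must be uniform")
  if (check_endpoints && (abs(p[1]) > 1e-9 || abs(p[length(p)]) > 1e-9))
    stop("p(0) and p(Dmax) must be zero")
  structure(list(r = r, p = p, dmax = dmax, alpha = alpha, chi2 = chi2),
            class = "PairDistribution")
}

# Non-negative least squares: Lawson-Hanson via pracma, with a cyclic
# coordinate-descent fallback (exact per-coordinate minimization of
# ||Mx - y||^2 over x >= 0) for systems where the active-set iteration cap
# is exceeded.
nnls_solve <- function(M, y) {
  out <- tryCatch(pracma::lsqnonneg(M, y)$x, error = function(e) NULL)
  if (!is.null(out)) return(out)
  G <- crossprod(M)
  b <- crossprod(M, y)
  n <- ncol(M)
  x <- rep(0, n)
  dg <- diag(G)
  dg[dg == 0] <- 1
  for (it in 1:2000) {
    delta <- 0
    for (j in 1:n) {
      xj <- max(0, x[j] + (b[j] - sum(G[j, ] * x)) / dg[j])
      delta <- max(delta, abs(xj - x[j]))
      x[j] <- xj
    }
    if (delta < 1e-10 * (max(x) + 1e-30)) break
  }
  x
}

ift_design <- function(q, r) {
  # A[i, j] = 4 pi dr sin(q_i r_j)/(q_i r_j); r_1 = 0 column is sinc = 1
  dr <- r[2] - r[1]
  x <- outer(q, r)
  S <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
  4 * pi * dr * S
}

#' P(r) by regularized indirect Fourier transform
#'
#' Solves `min ||(I - A p)/sigma||^2 + alpha ||D2 p||^2` subject to `p >= 0`
#' and `p(0) = p(Dmax) = 0`, on a uniform r grid, where
#' `A_ij = 4 pi dr sinc(q_i r_j)` and `D2` is the second-difference operator
#' (Tikhonov smoothing). The non-negative least-squares subproblem is solved
#' by the Lawson-Hanson algorithm (`pracma::lsqnonneg`).
#'
#' @param curve ScatteringCurve with sigma
#' @param dmax maximum dimension (Angstrom)
#' @param alpha regularization weight (> 0), or `NULL` to select it by the
#'   L-curve corner over a log grid
#' @param n_grid number of r grid points including both endpoints (default 51)
#' @return PairDistribution with back-computed reduced chi2
#' @export
pr_ift <- function(curve, dmax, alpha = NULL, n_grid = 51) {
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be > 0")
  q <- curve$q; I <- curve$I
  s <- curve$sigma
  if (all(is.na(s))) s <- rep(stats::sd(I) * 0.01 + 1e-12, length(I))
  if (dmax < 2 * pi / max(q) )
    warning("Dmax below the resolution limit 2*pi/qmax")
  r <- seq(0, dmax, length.out = n_grid)
  A <- ift_design(q, r)
  # unknowns: interior grid points (endpoints pinned at zero)
  int <- 2:(n_grid - 1)
  Aw <- A[, int, drop = FALSE] / s
  yw <- I / s
  # second differences over the full grid, endpoints at zero
  D2 <- matrix(0, n_grid - 2, n_grid)
  for (k in seq_len(n_grid - 2)) D2[k, k:(k + 2)] <- c(1, -2, 1)
  D2i <- D2[, int, drop = FALSE]
  sc <- sqrt(sum(Aw^2) / sum(D2i^2))  # balance the penalty against the data term
  solve_for <- function(a) {
    M <- rbind(Aw, sqrt(a) * sc * D2i)
    rhs <- c(yw, rep(0, nrow(D2i)))
    p <- numeric(n_grid)
    p[int] <- nnls_solve(M, rhs)
    resid <- (I - as.numeric(A %*% p)) / s
    list(p = p, chi2 = sum(resid^2) / (length(I) - 1),
         rough = sum((D2 %*% p)^2))
  }
  if (is.null(alpha)) {
    grid <- 10^seq(-8, 2, length.out = 11)
    sols <- lapply(grid, solve_for)
    lx <- log10(vapply(sols, `[[`, numeric(1), "chi2"))
    ly <- log10(vapply(sols, `[[`, numeric(1), "rough") + 1e-300)
    # L-curve corner: farthest point from the chord between the extremes
    v <- c(lx[length(lx)] - lx[1], ly[length(ly)] - ly[1])
    v <- v / sqrt(sum(v^2))
    d <- abs((lx - lx[1]) * v[2] - (ly - ly[1]) * v[1])
    k <- which.max(d)
    alpha <- grid[k]
    sol <- sols[[k]]
  } else {
    sol <- solve_for(alpha)
  }
  pair_distribution(r, sol$p, dmax, alpha = alpha, chi2 = sol$chi2)
}

#' Scan Dmax and pick the smallest adequate value
#'
#' For each candidate Dmax the constrained IFT is solved; the selected Dmax is
#' the smallest grid value whose fit chi2 is within `tol_factor` of the scan
#' minimum and whose unconstrained (ridge-only) solution stays non-negative at
#' Dmax within `neg_tol` of the peak height. This explicit rule stands in for
#' perceptual criteria used by interactive IFT programs.
#'
#' @param curve ScatteringCurve
#' @param dmax_grid candidate Dmax values (Angstrom)
#' @param alpha regularization weight used across the scan (default 1e-4, a
#'   light smoothing that keeps chi2 comparable between candidates; `NULL`
#'   re-selects alpha per candidate by L-curve)
#' @param tol_factor chi2 acceptance factor (default 1.05)
#' @param neg_tol allowed negative dip at Dmax, fraction of max p (default 0.1)
#' @param n_grid IFT grid size
#' @return list with `dmax`, `pr` (PairDistribution), `scan` (data.frame),
#'   `status`
#' @export
estimate_dmax <- function(curve, dmax_grid, alpha = 1e-4, tol_factor = 1.05,
                          neg_tol = 0.1, n_grid = 51) {
  q <- curve$q; I <- curve$I
  s <- curve$sigma
  if (all(is.na(s))) s <- rep(stats::sd(I) * 0.01 + 1e-12, length(I))
  scan <- data.frame(dmax = dmax_grid, chi2 = NA_real_, tail_ok = NA)
  prs <- vector("list", length(dmax_grid))
  for (i in seq_along(dmax_grid)) {
    D <- dmax_grid[i]
    pr <- pr_ift(curve, D, alpha = alpha, n_grid = n_grid)
    prs[[i]] <- pr
    scan$chi2[i] <- pr$chi2
    # unconstrained check: ridge solution with free tail, p(0) pinned
    r <- seq(0, D, length.out = n_grid)
    A <- ift_design(q, r)
    free <- 2:n_grid
    Aw <- A[, free, drop = FALSE] / s
    D2 <- matrix(0, n_grid - 2, n_grid)
    for (k in seq_len(n_grid - 2)) D2[k, k:(k + 2)] <- c(1, -2, 1)
    D2f <- D2[, free, drop = FALSE]
    a <- pr$alpha
    sc <- sqrt(sum(Aw^2) / sum(D2f^2))
    M <- rbind(Aw, sqrt(a) * sc * D2f)
    rhs <- c(I / s, rep(0, nrow(D2f)))
    x <- tryCatch(stats::lsfit(M, rhs, intercept = FALSE)$coefficients,
                  error = function(e) rep(NA_real_, length(free)))
    tail_val <- x[length(x)]
    scan$tail_ok[i] <- is.finite(tail_val) &&
      tail_val >= -neg_tol * max(abs(x), na.rm = TRUE)
  }
  best <- min(scan$chi2)
  ok <- which(scan$chi2 <= tol_factor * best & scan$tail_ok)
  if (length(ok) == 0)
    return(list(status = "failed", scan = scan, dmax = NA_real_, pr = NULL))
  sel <- ok[1]
  list(status = "ok", dmax = dmax_grid[sel], pr = prs[[sel]], scan = scan)
}

# --- Kratky and MW ----------------------------------------------------------

#' Dimensionless Kratky transform
#'
#' Pointwise transform to `x = q * Rg`, `y = (q Rg)^2 I(q) / I0`. For a
#' globular (Guinier-like) particle the curve peaks at `(sqrt(3), 3/e)`.
#'
#' @param curve ScatteringCurve
#' @param Rg radius of gyration (Angstrom, > 0)
#' @param I0 forward scattering (> 0)
#' @return data.frame with columns `x`, `y`
#' @export
dimensionless_kratky <- function(curve, Rg, I0) {
  if (Rg <= 0 || I0 <= 0) stop("Rg and I0 must be positive")
  x <- curve$q * Rg
  data.frame(x = x, y = x^2 * curve$I / I0)
}

#' Molecular weight from the volume of correlation
#'
#' `Vc = I0 / integral q I(q) dq` (trapezoid on the measured range with the
#' `[0, qmin)` head integrated analytically under the Guinier model), then
#' `QR = Vc^2 / Rg` and the empirical power law `MW(Da) = (QR / c)^k` with
#' the Rambo-Tainer protein constants `c = 0.1231, k = 1` (RNA: `c = 0.00934,
#' k = 0.808`). The method name and constants are always returned with the
#' value; the law is calibrated on globular proteins and is only indicative
#' for protein-RNA complexes.
#'
#' @param curve ScatteringCurve (q in 1/Angstrom)
#' @param guinier result of [guinier_fit()]
#' @param species `"protein"` (default) or `"rna"`
#' @param q_integration_max integrate q*I up to this q (default 0.3 1/A, the
#'   range over which the empirical constants were calibrated)
#' @param calibration `"relative"` (default; shape-based, intensity-scale
#'   invariant) or `"absolute"` (forward scattering on an absolute per-kDa
#'   scale: `MW = I0 / i0_per_kda`, requiring an instrument constant)
#' @param i0_per_kda absolute-mode instrument constant (I0 units per kDa)
#' @return list with `mw_kda`, `vc`, `qr`, `method`, `constants`, `coverage`
#' @export
mw_from_curve <- function(curve, guinier, species = c("protein", "rna"),
                          q_integration_max = 0.3,
                          calibration = c("relative", "absolute"),
                          i0_per_kda = NULL) {
  species <- match.arg(species)
  calibration <- match.arg(calibration)
  if (!identical(guinier$status, "ok")) stop("Guinier fit not valid")
  if (calibration == "absolute") {
    if (is.null(i0_per_kda) || i0_per_kda <= 0)
      stop("absolute calibration requires a positive i0_per_kda")
    return(list(mw_kda = guinier$I0 / i0_per_kda, vc = NA, qr = NA,
                method = "absolute_I0", constants = list(i0_per_kda =
                  i0_per_kda), coverage = NA))
  }
  if (!identical(guinier$status, "ok")) stop("Guinier fit not valid")
  Rg <- guinier$Rg; I0 <- guinier$I0
  keep <- curve$q <= q_integration_max
  q <- curve$q[keep]; I <- curve$I[keep]
  coverage <- max(q) / q_integration_max
  if (coverage < 0.8)
    warning(sprintf("q range covers only %.0f%% of the calibration range",
                    100 * coverage))
  # analytic head integral of q * I0 exp(-q^2 Rg^2 / 3) over [0, qmin]
  head_int <- I0 * 3 / (2 * Rg^2) * (1 - exp(-q[1]^2 * Rg^2 / 3))
  body_int <- sum(diff(q) * (q[-1] * I[-1] + q[-length(q)] * I[-length(I)]) / 2)
  vc <- I0 / (head_int + body_int)
  qr <- vc^2 / Rg
  const <- switch(species,
                  protein = list(c = 0.1231, k = 1.0),
                  rna = list(c = 0.00934, k = 0.808))
  mw <- (qr / const$c)^const$k / 1000  # power law yields Da; report kDa
  list(mw_kda = mw, vc = vc, qr = qr,
       method = "volume_of_correlation_power_law",
       constants = const, coverage = coverage)
}

# --- curves from coordinates ------------------------------------------------

#' P(r) histogram from coordinates
#'
#' Normalized pairwise-distance histogram (unit area); Dmax is the exact
#' maximum pairwise distance. Endpoint zeros are not enforced for histograms.
#'
#' @param model StructureModel
#' @param bin_width histogram bin width in Angstrom (default 2)
#' @param include_hydrogens include H atoms (default FALSE)
#' @return PairDistribution (histogram flavour)
#' @export
pr_from_structure <- function(model, bin_width = 2,
                              include_hydrogens = FALSE) {
  at <- model$atoms
  if (!include_hydrogens) at <- at[at$elesy != "H", , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (nrow(xyz) < 2) stop("need at least 2 atoms")
  d <- as.numeric(stats::dist(xyz))
  dmax <- max(d)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  p <- h$density
  pair_distribution(h$mids, p, dmax, alpha = NA, chi2 = NA,
                    check_endpoints = FALSE)
}

bead_coords <- function(model, bead = c("residue", "atom")) {
  bead <- match.arg(bead)
  at <- model$atoms[model$atoms$elesy != "H", , drop = FALSE]
  if (bead == "atom") return(as.matrix(at[, c("x", "y", "z")]))
  key <- paste(at$chain, at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  cakey <- paste(ca$chain, ca$resno)
  rows <- lapply(split(seq_len(nrow(at)), key), function(idx) {
    k <- key[idx[1]]
    j <- match(k, cakey)
    if (!is.na(j)) as.numeric(ca[j, c("x", "y", "z")])
    else colMeans(at[idx, c("x", "y", "z"), drop = FALSE])
  })
  do.call(rbind, rows)
}

#' Theoretical scattering by the Debye formula
#'
#' Coarse-grained profile `I(q) = sum_i sum_j f_i f_j sinc(q d_ij)` with one
#' bead per residue (Calpha, or the residue centre when no Calpha exists) and
#' a constant form factor. The `i = j` and `q -> 0` limits are handled
#' analytically: `I(0) = (sum f)^2`.
#'
#' @param model StructureModel
#' @param q q grid (1/Angstrom)
#' @param bead `"residue"` (default) or `"atom"`
#' @param f constant form factor per bead (default 1)
#' @return ScatteringCurve (sigma NA)
#' @export
debye_curve <- function(model, q, bead = "residue", f = 1) {
  xyz <- bead_coords(model, bead)
  n <- nrow(xyz)
  if (n == 1) return(scattering_curve(q, rep(f^2, length(q)),
                                      label = model$model_id))
  d <- as.numeric(stats::dist(xyz))
  x <- outer(q, d)
  sinc <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
  I <- n * f^2 + 2 * f^2 * rowSums(sinc)
  scattering_curve(q, I, label = model$model_id)
}

# --- multi-state fitting ----------------------------------------------------

#' Sparse multi-state fit of candidate curves to an experimental curve
#'
#' For every candidate subset of size up to `max_states`, non-negative weights
#' and a global scale are fit by non-negative least squares on the
#' sigma-weighted system, minimizing the reduced chi-square
#' `chi2 = 1/(N-1) sum((I_exp - c sum_k w_k I_k)^2 / sigma^2)` (N-1 degrees of
#' freedom, FoXS convention). The reported solution is the best subset of the
#' smallest size whose chi2 is within `within` (default 5%) of the global
#' best.
#'
#' @param curve experimental ScatteringCurve with sigma
#' @param candidates list of ScatteringCurve (resampled onto the experimental
#'   grid by linear interpolation, with a warning, when grids differ)
#' @param max_states maximum number of states (clamped to the candidate count
#'   with a warning)
#' @param within relative chi2 slack for preferring fewer states (default 0.05)
#' @return list with `states` (candidate indices), `weights` (sum 1), `scale`,
#'   `chi2`, and `by_size` (best fit per subset size)
#' @export
multi_state_fit <- function(curve, candidates, max_states = 3,
                            within = 0.05) {
  q <- curve$q; I <- curve$I; s <- curve$sigma
  if (all(is.na(s))) s <- rep(1, length(I))
  mats <- lapply(candidates, function(cc) {
    if (length(cc$q) != length(q) || any(abs(cc$q - q) > 1e-10)) {
      warning("candidate resampled onto the experimental q grid")
      stats::approx(cc$q, cc$I, xout = q, rule = 2)$y
    } else cc$I
  })
  B <- do.call(cbind, mats)
  m <- ncol(B)
  if (max_states > m) {
    warning("max_states clamped to the number of candidates (", m, ")")
    max_states <- m
  }
  fit_subset <- function(idx) {
    M <- B[, idx, drop = FALSE] / s
    w <- nnls_solve(M, I / s)
    resid <- (I - as.numeric(B[, idx, drop = FALSE] %*% w)) / s
    list(idx = idx, w = w, chi2 = sum(resid^2) / (length(I) - 1))
  }
  by_size <- list()
  for (k in seq_len(max_states)) {
    subsets <- utils::combn(m, k, simplify = FALSE)
    fits <- lapply(subsets, fit_subset)
    chi <- vapply(fits, `[[`, numeric(1), "chi2")
    by_size[[k]] <- fits[[which.min(chi)]]
  }
  chis <- vapply(by_size, `[[`, numeric(1), "chi2")
  best <- min(chis)
  k_sel <- which(chis <= (1 + within) * best)[1]
  sel <- by_size[[k_sel]]
  scale <- sum(sel$w)
  keep <- sel$w > 1e-12 * max(sel$w)
  list(states = sel$idx[keep],
       weights = sel$w[keep] / scale,
       scale = scale,
       chi2 = sel$chi2,
       by_size = data.frame(k = seq_along(chis), chi2 = chis))
}
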