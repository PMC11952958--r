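# ---------------------------------------------------------------------------
# Synthetic-data generators. Every generator takes an explicit integer seed,
# is bit-reproducible under it, and returns (or writes) a machine-readable
# ground-truth record alongside the data, so that recovery by the analysis
# operations can be asserted. Defaults encode the study conditions the
# analyses were designed around: 1% relative Gaussian noise on scattering,
# 3 replicates at 20% CV for cross-link quantitation, 165 +/- 10 Angstrom
# bead spacing, and so on.
# ---------------------------------------------------------------------------

#' Derive an independent sub-seed for a named stream
#'
#' One global seed fans out to per-generator streams so scenarios compose
#' without correlation. Rule: a polynomial hash of the stream name (base 31)
#' is mixed with `seed * 7919` modulo 2^31 - 2, plus 1; documented so runs are
#' reproducible across machines.
#'
#' @param seed integer global seed
#' @param name stream name
#' @return integer sub-seed in 1..2^31-1
#' @export
sub_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483646 + 1)
}

# --- analytic shapes ---------------------------------------------------------

sphere_amplitude <- function(q, R) {
  x <- q * R
  ifelse(x == 0, 1, 3 * (sin(x) - x * cos(x)) / ifelse(x == 0, 1, x^3))
}

#' Analytic p(r) of a uniform sphere
#' @param r distances (Angstrom)
#' @param R sphere radius
#' @return unnormalized p(r), zero outside [0, 2R]
#' @export
sphere_pr <- function(r, R) {
  x <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  p[r < 0 | r > 2 * R] <- 0
  p
}

#' Generate a noisy synthetic scattering curve with known truth
#'
#' Shapes: `"sphere"` (radius `R`), `"dumbbell"` (two identical spheres of
#' radius `R` with centres `d` apart), or `"structure"` (Debye curve of a
#' model). Noise is relative Gaussian with a floor:
#' `sigma(q) = max(rel * I(q), floor)`, mimicking the shape of counting
#' statistics without modelling the detector.
#'
#' @param shape `"sphere"`, `"dumbbell"` or `"structure"`
#' @param params list: `R` (and `d` for dumbbell; `model` for structure;
#'   optional `I0`, default 100)
#' @param q q grid (default `seq(0.005, 0.30, by = 0.001)` 1/Angstrom)
#' @param noise_rel relative noise (default 0.01); 0 gives a noiseless curve
#' @param noise_floor absolute sigma floor (default `1e-6 * I0`)
#' @param seed integer seed
#' @return list with `curve` (ScatteringCurve) and `truth`
#'   (`Rg`, `dmax`, `I0`, shape parameters)
#' @export
gen_curve <- function(shape = c("sphere", "dumbbell", "structure"),
                      params = list(R = 50),
                      q = seq(0.005, 0.30, by = 0.001),
                      noise_rel = 0.01, noise_floor = NULL, seed = 1) {
  shape <- match.arg(shape)
  I0 <- params$I0 %||% 100
  if (shape == "sphere") {
    R <- params$R
    I <- I0 * sphere_amplitude(q, R)^2
    truth <- list(shape = shape, R = R, Rg = R * sqrt(3 / 5), dmax = 2 * R,
                  I0 = I0)
  } else if (shape == "dumbbell") {
    R <- params$R; d <- params$d
    F2 <- sphere_amplitude(q, R)^2
    I <- I0 / 2 * F2 * (1 + sin(q * d) / (q * d))  # I(0) = I0
    # Rg^2 of two identical spheres at +/- d/2: Rg_sphere^2 + (d/2)^2
    truth <- list(shape = shape, R = R, d = d,
                  Rg = sqrt(3 / 5 * R^2 + (d / 2)^2), dmax = 2 * R + d,
                  I0 = I0)
  } else {
    model <- params$model
    base <- debye_curve(model, q, f = 1)
    I <- I0 * base$I / max(base$I)  # scaled so the q->0 plateau is ~I0
    xyz <- bead_coords(model)
    com <- colMeans(xyz)
    Rg <- sqrt(mean(rowSums(sweep(xyz, 2, com)^2)))
    truth <- list(shape = shape, Rg = Rg,
                  dmax = max(stats::dist(xyz)), I0 = I0)
  }
  if (is.null(noise_floor)) noise_floor <- 1e-6 * I0
  sigma <- pmax(noise_rel * abs(I), noise_floor)
  set.seed(seed)
  In <- I + if (noise_rel > 0) stats::rnorm(length(q), 0, sigma) else 0
  list(curve = scattering_curve(q, In, sigma, label = shape), truth = truth)
}

#' Generate a SEC-SAXS frame stack with buffer and sample frames
#'
#' Buffer frames carry a flat background; sample frames add the shape signal.
#' The reduced truth (signal only) is returned for recovery checks.
#'
#' @param shape,params,q as in [gen_curve()]
#' @param n_sample,n_buffer frame counts (default 10 each)
#' @param background flat buffer level (default 20)
#' @param noise_rel per-frame relative noise (default 0.02)
#' @param seed integer seed
#' @return list with `frames`, `buffer_ids`, `sample_ids`, `truth_curve`
#' @export
gen_sec_frames <- function(shape = "sphere", params = list(R = 50),
                           q = seq(0.005, 0.30, by = 0.002),
                           n_sample = 10, n_buffer = 10, background = 20,
                           noise_rel = 0.02, seed = 1) {
  clean <- gen_curve(shape, params, q, noise_rel = 0, seed = seed)
  signal <- clean$curve$I
  set.seed(sub_seed(seed, "sec_frames"))
  sigma <- pmax(noise_rel * (signal + background), 1e-6)
  frames <- vector("list", n_buffer + n_sample)
  for (i in seq_len(n_buffer))
    frames[[i]] <- scattering_curve(
      q, background + stats::rnorm(length(q), 0, noise_rel * background),
      rep(noise_rel * background, length(q)), label = paste0("buffer", i))
  for (i in seq_len(n_sample))
    frames[[n_buffer + i]] <- scattering_curve(
      q, signal + background + stats::rnorm(length(q), 0, sigma),
      sigma, label = paste0("sample", i))
  list(frames = frames, buffer_ids = seq_len(n_buffer),
       sample_ids = n_buffer + seq_len(n_sample),
       truth_curve = clean$curve, truth = clean$truth)
}

# --- fixture structures ------------------------------------------------------

#' Generate a Calpha-only fixture structure
#'
#' Kinds: `"helix"` (an idealized alpha-helical trace: rise 1.5 A, radius
#' 2.3 A, 100 degrees/residue), `"cloud"` (uniform random points in a sphere),
#' `"two_domain"` (two clouds separated along x). Chains are labelled from
#' `"A"`.
#'
#' @param kind fixture kind
#' @param n_res residues per chain (default 50)
#' @param n_chains number of chains (default 1)
#' @param radius cloud radius or domain separation scale (Angstrom)
#' @param seed integer seed
#' @return StructureModel
#' @export
make_fixture_structure <- function(kind = c("helix", "cloud", "two_domain"),
                                   n_res = 50, n_chains = 1, radius = 20,
                                   seed = 1) {
  kind <- match.arg(kind)
  set.seed(sub_seed(seed, paste0("fixture_", kind)))
  chains <- LETTERS[seq_len(n_chains)]
  rows <- list()
  for (ci in seq_along(chains)) {
    if (kind == "helix") {
      i <- seq_len(n_res)
      ang <- i * 100 * pi / 180
      xyz <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
      xyz[, 1] <- xyz[, 1] + (ci - 1) * 15
    } else if (kind == "cloud") {
      xyz <- matrix(stats::rnorm(3 * n_res), ncol = 3)
      xyz <- xyz / sqrt(rowSums(xyz^2)) *
        radius * stats::runif(n_res)^(1 / 3)
      xyz[, 1] <- xyz[, 1] + (ci - 1) * 3 * radius
    } else {
      half <- ceiling(n_res / 2)
      c1 <- matrix(stats::rnorm(3 * half), ncol = 3)
      c1 <- c1 / sqrt(rowSums(c1^2)) * radius * stats::runif(half)^(1 / 3)
      c2 <- matrix(stats::rnorm(3 * (n_res - half)), ncol = 3)
      c2 <- c2 / sqrt(rowSums(c2^2)) *
        radius * stats::runif(n_res - half)^(1 / 3)
      c2[, 1] <- c2[, 1] + 4 * radius
      xyz <- rbind(c1, c2)
      xyz[, 2] <- xyz[, 2] + (ci - 1) * 3 * radius
    }
    rows[[ci]] <- data.frame(chain = chains[ci], resno = seq_len(n_res),
                             resid = "ALA", elety = "CA", elesy = "C",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1)
  }
  structure_model(do.call(rbind, rows),
                  model_id = paste0("fixture_", kind))
}

#' Generate a toy crystal fixture with P2_1-like symmetry
#'
#' A small Calpha model in a cell with operators `X,Y,Z` and `-X,Y+1/2,-Z`,
#' for exercising symmetry expansion and symmetry-aware distance mapping.
#'
#' @param n_res residues (default 12)
#' @param cell unit cell (default `c(40, 40, 40, 90, 90, 90)`)
#' @param seed integer seed
#' @return StructureModel with cell and symops
#' @export
make_crystal_fixture <- function(n_res = 12,
                                 cell = c(40, 40, 40, 90, 90, 90),
                                 seed = 1) {
  set.seed(sub_seed(seed, "crystal_fixture"))
  xyz <- matrix(stats::runif(3 * n_res, 5, 15), ncol = 3)
  atoms <- data.frame(chain = "A", resno = seq_len(n_res), resid = "ALA",
                      elety = "CA", elesy = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1)
  structure_model(atoms, cell = cell,
                  symops = list(parse_symop("X,Y,Z"),
                                parse_symop("-X,Y+1/2,-Z")),
                  model_id = "crystal_fixture")
}

# --- cross-link tables -------------------------------------------------------

#' Generate a two-condition cross-link intensity table with planted truth
#'
#' True links are sampled from Calpha pairs at distance <= `cutoff` on the
#' fixture structure, decoys from pairs beyond it. Replicate areas are
#' log-normal around condition means set by the planted fold changes
#' (condition B mean = FC x condition A mean), with coefficient of variation
#' `cv`.
#'
#' @param model StructureModel (single chain is fine; sites carry the
#'   protein label)
#' @param protein protein label used for both sites (default `"P1"`)
#' @param n_true,n_decoy link counts in each distance class
#' @param cutoff distance class boundary (default 24 Angstrom)
#' @param planted_fc fold changes, recycled over the `n_true + n_decoy`
#'   features (default 1)
#' @param conditions condition labels (default `c("control", "rna")`)
#' @param n_replicates replicates per condition (default 3)
#' @param cv replicate coefficient of variation (default 0.2)
#' @param base_intensity condition-A mean area (default 1e6)
#' @param seed integer seed
#' @param path optional CSV output path
#' @return list with `features` (schema-carrying table), `schema`, `truth`
#'   (per-feature distance, planted FC, distance class), and `path` when
#'   written
#' @export
gen_crosslink_table <- function(model, protein = "P1", n_true = 10,
                                n_decoy = 10, cutoff = 24, planted_fc = 1,
                                conditions = c("control", "rna"),
                                n_replicates = 3, cv = 0.2,
                                base_intensity = 1e6, seed = 1, path = NULL) {
  set.seed(sub_seed(seed, "crosslinks"))
  ca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  dvec <- dm[upper.tri(dm)]
  short <- which(dvec > 0 & dvec <= cutoff)
  long <- which(dvec > cutoff)
  if (length(short) < n_true || length(long) < n_decoy)
    stop("structure offers only ", length(short), " pairs <= cutoff and ",
         length(long), " beyond it")
  pick_true <- sample(short, n_true)
  pick_decoy <- sample(long, n_decoy)
  pick <- c(pick_true, pick_decoy)
  n <- length(pick)
  fc <- rep_len(planted_fc, n)
  sdlog <- sqrt(log(1 + cv^2))
  intens <- function(mean_area, nrep)
    stats::rlnorm(nrep, log(mean_area) - sdlog^2 / 2, sdlog)
  tab <- data.frame(
    ProteinA = protein,
    ResidueA = ca$resno[pairs[pick, 1]],
    ProteinB = protein,
    ResidueB = ca$resno[pairs[pick, 2]])
  for (r in seq_len(n_replicates))
    tab[[paste0(conditions[1], "_", r)]] <-
      vapply(seq_len(n), function(i) intens(base_intensity, 1), numeric(1))
  for (r in seq_len(n_replicates))
    tab[[paste0(conditions[2], "_", r)]] <-
      vapply(seq_len(n), function(i) intens(base_intensity * fc[i], 1),
             numeric(1))
  schema <- crosslink_schema(
    "ProteinA", "ResidueA", "ProteinB", "ResidueB",
    conditions = stats::setNames(
      lapply(conditions, function(cc)
        paste0(cc, "_", seq_len(n_replicates))), conditions))
  truth <- data.frame(distance = dvec[pick],
                      planted_fc = fc,
                      class = rep(c("true", "decoy"), c(n_true, n_decoy)))
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         dataframe = "columns", digits = NA)
  }
  feats <- tab
  names(feats)[1:4] <- c("protein_a", "residue_a", "protein_b", "residue_b")
  feats$charge <- NA
  feats$modification <- NA
  attr(feats, "schema") <- schema
  list(features = feats, table = tab, schema = schema, truth = truth,
       path = path)
}

# --- variant tracks ----------------------------------------------------------

#' Generate a missense-variant set with planted per-domain depletion
#'
#' Per-residue variant counts are Poisson with rate `baseline_rate x factor`,
#' where `factor` comes from the domain table (1 outside all domains).
#'
#' @param protein_length residues
#' @param domains data.frame `label`, `start`, `end`, `factor` (may be empty)
#' @param baseline_rate expected variants per residue (default 0.2)
#' @param seed integer seed
#' @return list with `variants` (VariantSet), `truth` (rates per domain)
#' @export
gen_variant_track <- function(protein_length, domains = NULL,
                              baseline_rate = 0.2, seed = 1) {
  if (baseline_rate < 0) stop("rates must be >= 0")
  set.seed(sub_seed(seed, "variants"))
  rate <- rep(baseline_rate, protein_length)
  if (!is.null(domains) && nrow(domains) > 0)
    for (i in seq_len(nrow(domains)))
      rate[domains$start[i]:domains$end[i]] <-
        baseline_rate * domains$factor[i]
  counts <- stats::rpois(protein_length, rate)
  pos <- rep(seq_len(protein_length), counts)
  allele <- unlist(lapply(counts[counts > 0], seq_len), use.names = FALSE)
  change <- if (length(pos) > 0) paste0("p", pos, "v", allele)
            else character(0)
  vs <- variant_set("SYN1", pos, change = change,
                    protein_length = protein_length)
  list(variants = vs,
       truth = list(baseline_rate = baseline_rate, domains = domains,
                    total = sum(counts)))
}

# --- mass events -------------------------------------------------------------

#' Generate mass-photometry events from known stoichiometries
#'
#' @param stoich data.frame `n_protein`, `n_rna`, `fraction` (fractions sum
#'   to 1)
#' @param m_protein,m_rna component masses (kDa)
#' @param sigma Gaussian mass error per event (kDa, default 8)
#' @param n number of events (default 2000)
#' @param seed integer seed
#' @return list with `events` (numeric kDa) and `truth` (component masses and
#'   composition means)
#' @export
gen_mass_events <- function(stoich, m_protein, m_rna, sigma = 8, n = 2000,
                            seed = 1) {
  if (abs(sum(stoich$fraction) - 1) > 1e-9)
    stop("fractions must sum to 1")
  set.seed(sub_seed(seed, "mass_events"))
  means <- stoich$n_protein * m_protein + stoich$n_rna * m_rna
  comp <- sample(seq_len(nrow(stoich)), n, replace = TRUE,
                 prob = stoich$fraction)
  events <- stats::rnorm(n, means[comp], sigma)
  list(events = events,
       truth = list(means = means, fractions = stoich$fraction,
                    sigma = sigma, m_protein = m_protein, m_rna = m_rna))
}

# --- bead strings ------------------------------------------------------------

#' Generate jittered bead-on-string particle layouts
#'
#' Strings are laid out along random directions in the plane; consecutive
#' centre spacings, bead lengths and widths are Gaussian around the given
#' means (defaults match negative-stain observations of paired complexes on
#' long duplex RNA: spacing 165 +/- 10, length 160 +/- 15, width 130 +/- 15
#' Angstrom).
#'
#' @param n_strings number of strings (default 50)
#' @param beads_per_string beads per string (default 5)
#' @param spacing_mean,spacing_sd centre-to-centre spacing (Angstrom)
#' @param length_mean,length_sd bead length (Angstrom)
#' @param width_mean,width_sd bead width (Angstrom)
#' @param seed integer seed
#' @return list with `measurements` (data.frame with `units` attribute) and
#'   `truth`
#' @export
gen_bead_strings <- function(n_strings = 50, beads_per_string = 5,
                             spacing_mean = 165, spacing_sd = 10,
                             length_mean = 160, length_sd = 15,
                             width_mean = 130, width_sd = 15, seed = 1) {
  if (spacing_mean <= 0 || length_mean <= 0 || width_mean <= 0)
    stop("scales must be positive")
  set.seed(sub_seed(seed, "bead_strings"))
  rows <- list()
  for (s in seq_len(n_strings)) {
    th <- stats::runif(1, 0, 2 * pi)
    dirv <- c(cos(th), sin(th))
    origin <- stats::runif(2, 0, 5000)
    gaps <- stats::rnorm(beads_per_string - 1, spacing_mean, spacing_sd)
    pos <- c(0, cumsum(gaps))
    rows[[s]] <- data.frame(
      string_id = s, bead_index = seq_len(beads_per_string),
      x = origin[1] + pos * dirv[1], y = origin[2] + pos * dirv[2],
      length = stats::rnorm(beads_per_string, length_mean, length_sd),
      width = stats::rnorm(beads_per_string, width_mean, width_sd))
  }
  meas <- do.call(rbind, rows)
  attr(meas, "units") <- "angstrom"
  list(measurements = meas,
       truth = list(spacing_mean = spacing_mean, spacing_sd = spacing_sd,
                    length_mean = length_mean, width_mean = width_mean))
}
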