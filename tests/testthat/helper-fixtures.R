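# Shared fixtures and independent brute-force oracles used across the suite.

# minimal atom table builder
atoms_df <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                     elety = "CA", resid = "ALA", elesy = "C") {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1)
}

point_model <- function(xyz, ...) structure_model(atoms_df(xyz, ...))

# brute-force O(n^2) maximum pairwise distance
brute_max_dist <- function(xyz) {
  mx <- 0
  for (i in seq_len(nrow(xyz) - 1))
    for (j in (i + 1):nrow(xyz))
      mx <- max(mx, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  mx
}

# brute-force fold-change classifier mirroring the stated rule
brute_classify <- function(A, B, thr = 2, min_rep = 2) {
  nA <- sum(!is.na(A)); nB <- sum(!is.na(B))
  if (nA > 0 && nB > 0) {
    fc <- mean(B, na.rm = TRUE) / mean(A, na.rm = TRUE)
    if (fc >= thr) return("B_enriched")
    if (fc <= 1 / thr) return("A_enriched")
    return("common")
  }
  if (nA == 0 && nB >= min_rep) return("B_enriched")
  if (nB == 0 && nA >= min_rep) return("A_enriched")
  "unquantified"
}

# brute-force minimum distance between two sites over symmetry copies of a
# crystal model (enumerates every operator x lattice shift for both sites)
brute_sym_min_dist <- function(model, chain_a, res_a, chain_b, res_b,
                               lattice_range = 2) {
  M <- cell_matrix(model$cell)
  pa <- residue_anchor(model, chain_a, res_a)
  pb <- residue_anchor(model, chain_b, res_b)
  fa <- solve(M) %*% pa
  fb <- solve(M) %*% pb
  sh <- expand.grid(-lattice_range:lattice_range, -lattice_range:lattice_range,
                    -lattice_range:lattice_range)
  best <- Inf
  for (oa in model$symops) for (ob in model$symops) {
    f1 <- as.numeric(oa$R %*% fa) + oa$t
    f2 <- as.numeric(ob$R %*% fb) + ob$t
    for (i in seq_len(nrow(sh))) for (j in seq_len(nrow(sh))) {
      x1 <- M %*% (f1 + as.numeric(sh[i, ]))
      x2 <- M %*% (f2 + as.numeric(sh[j, ]))
      best <- min(best, sqrt(sum((x1 - x2)^2)))
    }
  }
  best
}

default_q <- seq(0.005, 0.30, by = 0.001)
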