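mini_schema <- function() crosslink_schema(
  "ProteinA", "ResidueA", "ProteinB", "ResidueB",
  conditions = list(control = paste0("control_", 1:3),
                    rna = paste0("rna_", 1:3)))

test_that("load_crosslinks parses rows, merges duplicates, tolerates bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ProteinA,ResidueA,ProteinB,ResidueB,control_1,control_2,control_3,rna_1,rna_2,rna_3",
    "NF45,194,NF90,214,100,110,90,400,420,380",
    "NF45,194,NF90,214,10,10,10,20,20,20",
    "NF45,xx,NF90,300,1,1,1,1,1,1",
    "NF45,186,NF90,298,50,NA,55,45,50,60"), path)
  expect_warning(f <- load_crosslinks(path, mini_schema()), "merged")
  expect_equal(nrow(f), 2)
  merged <- f[f$residue_a == 194, ]
  expect_equal(merged$control_1, 110)  # 100 + 10
  expect_equal(merged$rna_3, 400)      # 380 + 20
  errs <- attr(f, "errors")
  expect_equal(errs$row, 3)
  # single-row fixture parses to one feature
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ProteinA,ResidueA,ProteinB,ResidueB,control_1,control_2,control_3,rna_1,rna_2,rna_3",
    "NF45,190,NF90,214,1,2,3,4,5,6"), path2)
  f2 <- load_crosslinks(path2, mini_schema())
  expect_equal(nrow(f2), 1)
  expect_equal(f2$protein_a, "NF45")
  expect_equal(f2$residue_b, 214L)
})

test_that("column order is irrelevant under a schema-driven parse", {
  rowv <- c(ResidueB = "214", control_1 = "1", control_2 = "2",
            control_3 = "3", ProteinA = "NF45", rna_1 = "9", rna_2 = "9",
            rna_3 = "9", ResidueA = "194", ProteinB = "NF90")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(names(rowv), collapse = ","),
               paste(rowv, collapse = ",")), p1)
  perm <- sample(length(rowv))
  writeLines(c(paste(names(rowv)[perm], collapse = ","),
               paste(rowv[perm], collapse = ",")), p2)
  f1 <- load_crosslinks(p1, mini_schema())
  f2 <- load_crosslinks(p2, mini_schema())
  expect_equal(f1[names(f1)], f2[names(f1)])
})

test_that("classify_quant applies the fold-change rule with its stated boundaries", {
  mk <- function(ctrl, rna) {
    f <- data.frame(protein_a = "P", residue_a = 1, protein_b = "P",
                    residue_b = 2, charge = NA, modification = NA)
    for (i in 1:3) f[[paste0("control_", i)]] <- ctrl[i]
    for (i in 1:3) f[[paste0("rna_", i)]] <- rna[i]
    attr(f, "schema") <- mini_schema()
    f
  }
  # equal means -> common, FC = 1
  c1 <- classify_quant(mk(c(100, 100, 100), c(100, 100, 100)),
                       c("control", "rna"))
  expect_equal(as.character(c1$category), "common")
  expect_equal(c1$fc, 1)
  # means 100 vs 250 -> RNA-enriched at threshold 2
  c2 <- classify_quant(mk(c(100, 100, 100), c(250, 250, 250)),
                       c("control", "rna"))
  expect_equal(as.character(c2$category), "B_enriched")
  expect_equal(c2$fc, 2.5)
  # detected in one condition only
  c3 <- classify_quant(mk(c(NA, NA, NA), c(50, 60, NA)), c("control", "rna"))
  expect_equal(as.character(c3$category), "B_enriched")
  expect_true(c3$one_condition_only)
  expect_equal(c3$fc, Inf)
  c4 <- classify_quant(mk(c(NA, NA, NA), c(50, NA, NA)), c("control", "rna"))
  expect_equal(as.character(c4$category), "unquantified")
})

test_that("classification matches the brute-force rule on random tables and is symmetric", {
  set.seed(31)
  n <- 60
  f <- data.frame(protein_a = "P", residue_a = seq_len(n), protein_b = "P",
                  residue_b = seq_len(n) + 100, charge = NA,
                  modification = NA)
  for (i in 1:3) f[[paste0("control_", i)]] <-
    ifelse(runif(n) < 0.15, NA, rlnorm(n, log(100), 0.8))
  for (i in 1:3) f[[paste0("rna_", i)]] <-
    ifelse(runif(n) < 0.15, NA, rlnorm(n, log(100), 0.8))
  attr(f, "schema") <- mini_schema()
  cls <- classify_quant(f, c("control", "rna"))
  expected <- vapply(seq_len(n), function(i)
    brute_classify(as.numeric(f[i, paste0("control_", 1:3)]),
                   as.numeric(f[i, paste0("rna_", 1:3)])), character(1))
  expect_equal(as.character(cls$category), expected)
  # relabeling conditions swaps the enriched classes exactly
  swapped <- classify_quant(f, c("rna", "control"))
  mapsw <- c(A_enriched = "B_enriched", B_enriched = "A_enriched",
             common = "common", unquantified = "unquantified")
  expect_equal(as.character(swapped$category),
               unname(mapsw[as.character(cls$category)]))
  # joint intensity scaling leaves FC unchanged
  f2 <- f
  for (cc in c(paste0("control_", 1:3), paste0("rna_", 1:3)))
    f2[[cc]] <- f[[cc]] * 3.7
  attr(f2, "schema") <- mini_schema()
  cls2 <- classify_quant(f2, c("control", "rna"))
  expect_equal(cls2$fc, cls$fc, tolerance = 1e-12)
  # categories partition the features
  expect_equal(sum(table(cls$category)), n)
})

test_that("planted enriched links are recovered and distances map exactly", {
  model <- make_fixture_structure("cloud", n_res = 60, radius = 30, seed = 5)
  g <- gen_crosslink_table(model, n_true = 10, n_decoy = 10,
                           planted_fc = c(rep(4, 5), rep(0.25, 5),
                                          rep(1, 10)),
                           cv = 0.2, seed = 5)
  cls <- classify_quant(g$features, c("control", "rna"))
  planted_up <- which(g$truth$planted_fc == 4)
  planted_dn <- which(g$truth$planted_fc == 0.25)
  hits <- sum(as.character(cls$category[planted_up]) == "B_enriched") +
    sum(as.character(cls$category[planted_dn]) == "A_enriched")
  expect_gte(hits, 9)
  rep_ <- map_distance(g$features, model, chain_map = list(P1 = "A"),
                       use_symmetry = FALSE)
  expect_equal(rep_$distance, g$truth$distance, tolerance = 1e-9)
  expect_true(all(rep_$satisfied[g$truth$class == "true"]))
  expect_false(any(rep_$satisfied[g$truth$class == "decoy"]))
})

test_that("map_distance: same-residue links are 0 A and unresolvable sites are non-fatal", {
  model <- make_fixture_structure("cloud", n_res = 20, seed = 2)
  f <- data.frame(protein_a = c("P1", "P1"), residue_a = c(5L, 999L),
                  protein_b = c("P1", "P1"), residue_b = c(5L, 1000L))
  rep_ <- map_distance(f, model, chain_map = list(P1 = "A"))
  expect_equal(rep_$distance[1], 0)
  expect_true(rep_$satisfied[1])
  expect_true(is.na(rep_$distance[2]))
  expect_match(rep_$status[2], "unresolvable")
})

test_that("symmetry-aware minimum equals brute force and never exceeds identity", {
  m <- make_crystal_fixture(n_res = 12, cell = c(30, 30, 30, 90, 90, 90),
                            seed = 11)
  f <- data.frame(protein_a = "P1", residue_a = c(1L, 3L, 5L),
                  protein_b = "P1", residue_b = c(7L, 9L, 12L))
  with_sym <- map_distance(f, m, chain_map = list(P1 = "A"),
                           use_symmetry = TRUE)
  no_sym <- map_distance(f, m, chain_map = list(P1 = "A"),
                         use_symmetry = FALSE)
  for (i in 1:3) {
    oracle <- brute_sym_min_dist(m, "A", f$residue_a[i], "A", f$residue_b[i],
                                 lattice_range = 1)
    expect_equal(with_sym$distance[i], oracle, tolerance = 1e-9)
    expect_lte(with_sym$distance[i], no_sym$distance[i] + 1e-9)
  }
})

test_that("a pair satisfied only via a symmetry mate flips with symmetry on", {
  # one atom near the cell origin, another near the far corner: the lattice
  # translate of the corner atom is close to the origin atom
  m <- structure_model(
    atoms_df(rbind(c(1, 1, 1), c(29, 29, 29)), resno = c(1, 2)),
    cell = c(30, 30, 30, 90, 90, 90),
    symops = list(parse_symop("X,Y,Z")))
  f <- data.frame(protein_a = "P1", residue_a = 1L,
                  protein_b = "P1", residue_b = 2L)
  d_on <- map_distance(f, m, list(P1 = "A"), use_symmetry = TRUE)$distance
  d_off <- map_distance(f, m, list(P1 = "A"), use_symmetry = FALSE)$distance
  expect_lt(d_on, d_off)
  expect_equal(d_on, sqrt(3 * 4), tolerance = 1e-9)  # (1,1,1) vs (-1,-1,-1)
  expect_equal(d_off, sqrt(3 * 28^2), tolerance = 1e-9)
})

test_that("evaluate_assemblies ranks a lateral assembly above the single copy", {
  unit <- make_fixture_structure("cloud", n_res = 40, radius = 15, seed = 8)
  lat <- build_lateral_oligomer(unit, n = 2, rise = 35)
  # plant inter-copy links: residues whose copies are within 24 A across units
  c1 <- lat$copies[[1]]; c2 <- lat$copies[[2]]
  x1 <- coords(c1); x2 <- coords(c2)
  d12 <- sqrt(pmax(outer(rowSums(x1^2), rowSums(x2^2), "+") -
                     2 * x1 %*% t(x2), 0))
  idx <- which(d12 <= 24 & d12 > 5, arr.ind = TRUE)
  idx <- idx[seq_len(min(6, nrow(idx))), , drop = FALSE]
  expect_gte(nrow(idx), 3)
  f <- data.frame(protein_a = "P1", residue_a = c1$atoms$resno[idx[, 1]],
                  protein_b = "P1", residue_b = c2$atoms$resno[idx[, 2]])
  res <- evaluate_assemblies(
    f,
    assemblies = list(single = list(model = unit, chain_map = list(P1 = "A")),
                      lateral = list(model = lat$assembly,
                                     chain_map = list(P1 = c("A.1", "A.2")))),
    cutoff = 24)
  tab <- res$table
  expect_gt(tab$fraction[tab$assembly == "lateral"],
            tab$fraction[tab$assembly == "single"])
  expect_equal(tab$rank[tab$assembly == "lateral"], 1)
  expect_equal(tab$fraction[tab$assembly == "lateral"], 1)
})

test_that("identical assemblies score identically and ranking ignores feature order", {
  unit <- make_fixture_structure("cloud", n_res = 30, radius = 20, seed = 14)
  g <- gen_crosslink_table(unit, n_true = 6, n_decoy = 6, seed = 14)
  res <- evaluate_assemblies(
    g$features, assemblies = list(m1 = unit, m2 = unit),
    chain_map = list(P1 = "A"))
  expect_equal(res$table$satisfied[1], res$table$satisfied[2])
  expect_equal(res$reports$m1$distance, res$reports$m2$distance)
  set.seed(1)
  perm <- sample(nrow(g$features))
  res2 <- evaluate_assemblies(
    g$features[perm, ], assemblies = list(m1 = unit, m2 = unit),
    chain_map = list(P1 = "A"))
  expect_equal(res2$table$fraction, res$table$fraction)
  expect_error(evaluate_assemblies(g$features, list(only = unit),
                                   chain_map = list(P1 = "A")),
               "at least 2")
})

test_that("restraint files round-trip through the documented format", {
  model <- make_fixture_structure("cloud", n_res = 20, radius = 15, seed = 3)
  g <- gen_crosslink_table(model, n_true = 4, n_decoy = 4, seed = 3)
  rep_ <- map_distance(g$features, model, chain_map = list(P1 = "A"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_restraints(g$features, rep_, path)
  back <- read.table(path)
  expect_equal(nrow(back), 8)
  expect_equal(back$V5, round(rep_$distance, 2))
  expect_equal(back$V6, rep_$satisfied)
})
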