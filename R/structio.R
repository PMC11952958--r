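#' @importFrom stats dist setNames
NULL

# ---------------------------------------------------------------------------
# StructureModel: a light container over an atom table, optionally carrying a
# unit cell and fractional symmetry operators so that crystallographic
# neighbour searches (symmetry expansion) can be performed.
# ---------------------------------------------------------------------------

#' Construct a StructureModel
#'
#' A `StructureModel` holds an atom table (chain, author residue number,
#' residue name, atom name, element, Cartesian coordinates in Angstrom,
#' occupancy), an optional unit cell `(a, b, c, alpha, beta, gamma)` and an
#' optional list of crystallographic symmetry operators expressed in
#' fractional coordinates.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`, `o`. Missing `elesy` is inferred from the first
#'   letter of `elety`; missing `o` defaults to 1.
#' @param cell optional numeric vector `c(a, b, c, alpha, beta, gamma)`
#'   (Angstrom / degrees).
#' @param symops optional list of operators, each `list(R = 3x3 matrix,
#'   t = length-3 vector)` acting on fractional coordinates. If supplied, the
#'   identity operator must appear exactly once.
#' @param model_id label for the model (default `"model1"`).
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(atoms, cell = NULL, symops = NULL,
                            model_id = "model1") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"elesy" %in% names(atoms))
    atoms$elesy <- toupper(substr(gsub("[0-9]", "", atoms$elety), 1, 1))
  if (!"o" %in% names(atoms)) atoms$o <- 1
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom name) address: ",
         key[duplicated(key)][1])
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6 || any(!is.finite(cell)) || any(cell[1:3] <= 0))
      stop("cell must be c(a, b, c, alpha, beta, gamma) with positive edges")
  }
  if (!is.null(symops)) {
    n_id <- sum(vapply(symops, function(op) {
      isTRUE(all.equal(op$R, diag(3), tolerance = 1e-9)) &&
        isTRUE(all.equal(as.numeric(op$t), c(0, 0, 0), tolerance = 1e-9))
    }, logical(1)))
    if (n_id != 1L)
      stop("symmetry operator list must contain the identity exactly once (found ",
           n_id, ")")
  }
  structure(list(atoms = atoms, cell = cell, symops = symops,
                 model_id = model_id),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel '", x$model_id, "': ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)",
      if (!is.null(x$cell)) " [crystal]", "\n", sep = "")
  invisible(x)
}

#' Coordinate matrix of a model
#' @param model StructureModel
#' @return n x 3 numeric matrix
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# --- symmetry operator string parsing --------------------------------------

#' Parse a symmetry operator string
#'
#' Parses crystallographic operator strings such as `"-X,Y+1/2,-Z"` into a
#' fractional-space rotation matrix and translation vector. Accepts upper or
#' lower case, optional whitespace, and fractions written as `p/q` or
#' decimals, on either side of the axis terms.
#'
#' @param s operator string with three comma-separated terms.
#' @return `list(R = 3x3 matrix, t = numeric(3))`
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", toupper(s)), ",")[[1]]
  if (length(parts) != 3) stop("operator must have 3 comma-separated terms: ", s)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    term <- parts[i]
    # tokenize into signed monomials
    toks <- regmatches(term, gregexpr("[+-]?[^+-]+", term))[[1]]
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      ax <- match(TRUE, c(grepl("X", body), grepl("Y", body), grepl("Z", body)))
      if (!is.na(ax)) {
        coefstr <- gsub("[XYZ*]", "", body)
        coef <- if (coefstr == "") 1 else eval(parse(text = coefstr))
        R[i, ax] <- R[i, ax] + sign * coef
      } else {
        t[i] <- t[i] + sign * eval(parse(text = body))
      }
    }
  }
  list(R = R, t = t)
}

# --- file IO ----------------------------------------------------------------

#' Read an atomic structure from PDB or mmCIF
#'
#' Atoms of the first model are returned; additional models trigger a warning.
#' Unit cell (CRYST1) and the fractional symmetry operators printed in REMARK
#' 290 are recorded when present. Altloc conformers are reduced to the
#' highest-occupancy one (ties broken by altloc letter order).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a [structure_model()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  cell <- NULL
  symops <- NULL
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    n_models <- sum(grepl("^MODEL ", lines))
    if (n_models > 1)
      warning("file has ", n_models, " models; first model used")
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr) >= 1) {
      f <- function(a, b) suppressWarnings(as.numeric(substr(cr[1], a, b)))
      cl <- c(f(7, 15), f(16, 24), f(25, 33), f(34, 40), f(41, 47), f(48, 54))
      if (all(is.finite(cl)) && all(cl[1:3] > 0)) cell <- cl
    }
    opl <- grep("^REMARK 290\\s+\\d+\\s+[-0-9XYZxyz/,.+ ]+$", lines,
                value = TRUE)
    opl <- opl[grepl("[XYZxyz]", opl)]
    if (length(opl) > 0) {
      ops <- sub("^REMARK 290\\s+\\d+\\s+", "", opl)
      symops <- lapply(ops, parse_symop)
    }
    pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e)
                      stop("PDB parse error in ", path, ": ",
                           conditionMessage(e)))
    at <- pdb$atom
  } else {
    pdb <- tryCatch(bio3d::read.cif(path, verbose = FALSE),
                    error = function(e)
                      stop("mmCIF parse error in ", path, ": ",
                           conditionMessage(e)))
    at <- pdb$atom
  }
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  # altloc reduction: keep highest occupancy, ties by altloc letter order
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$elety)
  if (any(alt != "")) {
    o <- at$o
    o[is.na(o)] <- 1
    ord <- order(key, -o, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  }
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      elesy = toupper(as.character(at$elesy)),
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  bad <- is.na(atoms$elesy) | atoms$elesy == ""
  atoms$elesy[bad] <- toupper(substr(gsub("[0-9]", "", atoms$elety[bad]), 1, 1))
  structure_model(atoms, cell = cell, symops = symops,
                  model_id = basename(path))
}

#' Write a StructureModel as PDB
#'
#' Writes CRYST1 and REMARK 290 operator lines when the model carries a cell
#' and symmetry operators, so that [read_structure()] round-trips them.
#'
#' @param model StructureModel. Chains longer than one character are mapped to
#'   successive single letters with a comment line recording the mapping.
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  lines <- character(0)
  if (!is.null(model$symops)) {
    for (k in seq_along(model$symops)) {
      op <- model$symops[[k]]
      lines <- c(lines, sprintf("REMARK 290 %6d   %s", k, format_symop(op)))
    }
  }
  if (!is.null(model$cell)) {
    cl <- model$cell
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cl[1], cl[2], cl[3], cl[4], cl[5], cl[6]))
  }
  at <- model$atoms
  ch <- as.character(at$chain)
  uch <- unique(ch)
  if (any(nchar(uch) > 1)) {
    repl <- setNames(strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ0123456789", "")[[1]][
      seq_along(uch)], uch)
    lines <- c(lines, paste0("REMARK  99 CHAIN MAP ",
                             paste(uch, repl[uch], sep = ">", collapse = " ")))
    ch <- repl[ch]
  }
  for (i in seq_len(nrow(at))) {
    nm <- at$elety[i]
    nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    lines <- c(lines, sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, nmfmt, substr(at$resid[i], 1, 3), ch[i], at$resno[i],
      at$x[i], at$y[i], at$z[i], at$o[i], 0, at$elesy[i]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

format_symop <- function(op) {
  ax <- c("X", "Y", "Z")
  terms <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      c_ <- op$R[i, j]
      if (abs(c_) > 1e-9) {
        sgn <- if (c_ < 0) "-" else if (nchar(s) > 0) "+" else ""
        co <- if (abs(abs(c_) - 1) < 1e-9) "" else paste0(abs(c_), "*")
        s <- paste0(s, sgn, co, ax[j])
      }
    }
    tv <- op$t[i]
    if (abs(tv) > 1e-9) {
      fr <- frac_string(tv)
      s <- paste0(s, if (tv > 0) "+" else "-", fr)
    }
    terms[i] <- s
  }
  paste(terms, collapse = ",")
}

frac_string <- function(x) {
  x <- abs(x)
  for (den in c(2, 3, 4, 6)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(paste0(round(num), "/", den))
  }
  format(x)
}

# --- addressing -------------------------------------------------------------

#' Anchor coordinates for a residue
#'
#' Returns the coordinates of the named atom (default `CA`) of the addressed
#' residue. If the residue lacks that atom (e.g. a ligand without a Calpha),
#' the geometric centre of the residue is returned with attribute
#' `anchor = "center"`.
#'
#' @param model StructureModel
#' @param chain chain label
#' @param resno author residue number
#' @param atom anchor atom name, default `"CA"`
#' @return numeric xyz (length 3); attribute `anchor` is `"atom"` or
#'   `"center"`.
#' @export
residue_anchor <- function(model, chain, resno, atom = "CA") {
  at <- model$atoms
  sel <- at$chain == chain & at$resno == resno
  if (!any(sel)) {
    have <- sort(unique(at$resno[at$chain == chain]))
    if (length(have) == 0)
      stop("chain '", chain, "' not present; chains: ",
           paste(unique(at$chain), collapse = ", "))
    stop("residue ", resno, " not in chain ", chain,
         " (present: ", min(have), "-", max(have), ")")
  }
  hit <- sel & at$elety == atom
  if (any(hit)) {
    xyz <- as.numeric(at[which(hit)[1], c("x", "y", "z")])
    attr(xyz, "anchor") <- "atom"
  } else {
    xyz <- colMeans(at[sel, c("x", "y", "z")])
    xyz <- as.numeric(xyz)
    attr(xyz, "anchor") <- "center"
  }
  xyz
}

# --- geometry ---------------------------------------------------------------

heavy_rows <- function(model) model$atoms$elesy != "H"

#' Maximum pairwise atomic distance (Dmax of a structure)
#'
#' Exact maximum Euclidean distance over all selected atom pairs. Hydrogens
#' are excluded by default, matching heavy-atom Dmax conventions.
#'
#' @param model StructureModel
#' @param selection optional logical/integer row selection into the atom table
#' @param include_hydrogens include H atoms (default FALSE)
#' @return distance in Angstrom
#' @export
max_pairwise_distance <- function(model, selection = NULL,
                                  include_hydrogens = FALSE) {
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!include_hydrogens) keep <- keep & heavy_rows(model)
  if (!is.null(selection)) {
    sel <- rep(FALSE, nrow(at))
    sel[selection] <- TRUE
    keep <- keep & sel
  }
  xyz <- as.matrix(at[keep, c("x", "y", "z")])
  if (nrow(xyz) < 2) stop("need at least 2 atoms for a pairwise distance")
  max(stats::dist(xyz))
}

#' Apply a rigid-body transform in Cartesian space
#'
#' @param model StructureModel
#' @param R 3x3 rotation matrix
#' @param t translation vector (Angstrom)
#' @param model_id label for the transformed copy
#' @return transformed StructureModel (cell/symops dropped)
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0),
                            model_id = paste0(model$model_id, "_t")) {
  xyz <- coords(model) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  at <- model$atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  structure_model(at, model_id = model_id)
}

#' Orthogonalization matrix of a unit cell
#'
#' Columns are the cell vectors in Cartesian Angstrom (PDB convention: a along
#' x, b in the xy plane). `x_cart = M %*% x_frac`.
#' @param cell numeric c(a, b, c, alpha, beta, gamma)
#' @return 3x3 matrix
#' @export
cell_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c_ * cos(be),
           0, b * sin(ga), c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c_ * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Crystallographic symmetry expansion around a point
#'
#' Applies every symmetry operator combined with integer lattice translations
#' in the block `[-lattice_range, lattice_range]^3` and returns each copy that
#' places at least one atom within `radius` of `center`. The identity copy is
#' always included. Each copy is tagged with its operator index and lattice
#' shift.
#'
#' @param model StructureModel with `cell` and `symops`
#' @param center xyz (Angstrom) around which neighbours are sought
#' @param radius search radius in Angstrom (must be finite)
#' @param lattice_range half-width of the lattice translation block (default 2)
#' @return list of entries `list(model, op_index, shift, is_identity)`
#' @export
symmetry_expand <- function(model, center, radius, lattice_range = 2) {
  if (is.null(model$cell))
    stop("model has no unit cell; run in single-copy mode (no expansion)")
  if (!is.finite(radius)) stop("radius must be finite")
  ops <- model$symops
  if (is.null(ops)) ops <- list(list(R = diag(3), t = c(0, 0, 0)))
  M <- cell_matrix(model$cell)
  Minv <- solve(M)
  frac <- coords(model) %*% t(Minv)
  shifts <- as.matrix(expand.grid(n1 = -lattice_range:lattice_range,
                                  n2 = -lattice_range:lattice_range,
                                  n3 = -lattice_range:lattice_range))
  out <- list()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    f1 <- frac %*% t(op$R)
    f1 <- sweep(f1, 2, op$t, "+")
    is_id <- isTRUE(all.equal(op$R, diag(3), tolerance = 1e-9)) &&
      isTRUE(all.equal(as.numeric(op$t), c(0, 0, 0), tolerance = 1e-9))
    for (s in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[s, ])
      f2 <- sweep(f1, 2, sh, "+")
      xyz <- f2 %*% t(M)
      d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
        (xyz[, 3] - center[3])^2
      identity_copy <- is_id && all(sh == 0)
      if (identity_copy || min(d2) <= radius^2) {
        at <- model$atoms
        at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
        out[[length(out) + 1]] <- list(
          model = structure_model(at, model_id = sprintf(
            "%s_op%d_%d.%d.%d", model$model_id, k, sh[1], sh[2], sh[3])),
          op_index = k, shift = sh, is_identity = identity_copy)
      }
    }
  }
  out
}
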