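# Coordinate models, atom selection, Kabsch superposition and crystal
# symmetry expansion. Atoms live in a plain data.frame; Cartesian angstroms
# everywhere except inside the fractional-space symmetry machinery.

#' Standard amino-acid residue names recognised as protein
#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "SEC", "PYL")

#' Noble-gas element symbols handled by the site analysis
#' @export
GAS_ELEMENTS <- c("AR", "KR", "XE")

#' Crystallographic unit cell
#'
#' @param a,b,c Cell edge lengths in angstroms (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  cell <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  class(cell) <- "unit_cell"
  # fractionalization must be well defined
  if (abs(det(orth_matrix(cell))) < 1e-8)
    stop("degenerate unit cell: orthogonalization matrix is singular")
  cell
}

#' Fractional-to-Cartesian (orthogonalization) matrix, PDB convention
#' @param cell A [unit_cell()].
#' @return 3x3 matrix M such that cartesian = M %*% fractional.
#' @export
orth_matrix <- function(cell) {
  al <- cell$alpha * pi / 180
  be <- cell$beta * pi / 180
  ga <- cell$gamma * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    cell$a, cell$b * cos(ga), cell$c * cos(be),
    0,      cell$b * sin(ga), cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0,      0,                cell$c * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

#' Cartesian-to-fractional matrix
#' @inheritParams orth_matrix
#' @export
frac_matrix <- function(cell) solve(orth_matrix(cell))

#' Crystallographic symmetry operator in fractional space
#'
#' @param rotation 3x3 matrix acting on fractional coordinates
#'   (determinant +1 or -1).
#' @param translation Fractional translation 3-vector.
#' @export
symop <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  d <- det(rotation)
  if (abs(abs(d) - 1) > 1e-6)
    stop("symop rotation must have determinant +1 or -1, got ", signif(d, 6))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "symop")
}

#' @rdname symop
#' @export
symop_identity <- function() symop(diag(3), c(0, 0, 0))

is_identity_op <- function(op, tol = 1e-9) {
  max(abs(op$rotation - diag(3))) < tol && max(abs(op$translation)) < tol
}

#' Parse symmetry operators from xyz triplet strings
#'
#' Accepts the International Tables style strings found in mmCIF files and
#' space-group references, e.g. `"-x,-y,z"` or `"x+1/2,-y+1/2,-z"`.
#'
#' @param strings Character vector of operator triplets.
#' @return List of [symop()] objects.
#' @export
symops_from_strings <- function(strings) {
  parse_one <- function(s) {
    parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
    if (length(parts) != 3) stop("malformed symmetry operator: ", s)
    rot <- matrix(0, 3, 3)
    tra <- numeric(3)
    for (i in 1:3) {
      expr <- parts[i]
      # coefficients of x, y, z
      for (j in 1:3) {
        v <- c("x", "y", "z")[j]
        if (grepl(paste0("-", v), expr, fixed = TRUE)) rot[i, j] <- -1
        else if (grepl(v, expr, fixed = TRUE)) rot[i, j] <- 1
      }
      # constant fraction like 1/2, 3/4 or decimals
      num <- gsub("[xyz]", "", expr)
      num <- gsub("\\+\\-", "-", gsub("^\\+|\\-$|\\+$", "", num))
      num <- gsub("(^|[+-])\\-", "\\1-", num)
      num <- gsub("[+-]$", "", num)
      num <- gsub("^([+-]?)$", "", num)
      if (nzchar(num)) {
        m <- regmatches(num, regexpr("[+-]?[0-9]+(/[0-9]+)?(\\.[0-9]+)?", num))
        if (length(m) && nzchar(m)) {
          if (grepl("/", m)) {
            pq <- as.numeric(strsplit(m, "/")[[1]])
            tra[i] <- pq[1] / pq[2]
          } else tra[i] <- as.numeric(m)
        }
      }
    }
    symop(rot, tra)
  }
  lapply(strings, parse_one)
}

#' Atomic coordinate model
#'
#' The coordinate universe for all geometry in the package: an ordered atom
#' table plus (optionally) the crystallographic unit cell and symmetry
#' operators needed to generate lattice neighbours.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`, `occ`, `b`, `type`
#'   ("ATOM"/"HETATM").
#' @param cell Optional [unit_cell()].
#' @param symops Optional list of [symop()]; the identity is added if absent.
#' @param label Free-text model label.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, symops = NULL, label = "") {
  req <- c("serial", "name", "element", "resname", "resno", "chain",
           "x", "y", "z", "occ", "b", "type")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  if (nrow(atoms)) {
    if (anyDuplicated(atoms$serial))
      stop("atom serial numbers must be unique")
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("atom positions must be finite")
    if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
      stop("occupancies must lie in [0, 1]")
    if (any(atoms$b < 0, na.rm = TRUE))
      stop("B-factors must be non-negative")
  }
  if (!is.null(symops)) {
    if (is.null(cell)) stop("symmetry operators require a unit cell")
    if (!any(vapply(symops, is_identity_op, logical(1))))
      symops <- c(list(symop_identity()), symops)
  }
  structure(list(atoms = atoms, cell = cell, symops = symops, label = label),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d residues%s%s\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              if (is.null(x$cell)) "" else ", with unit cell",
              if (is.null(x$symops)) "" else
                sprintf(", %d symops", length(x$symops))))
  invisible(x)
}

#' Cartesian coordinates of a model as an N x 3 matrix
#' @param model A [structure_model()].
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

n_atoms <- function(model) nrow(model$atoms)

# squared distances between every row of a and every row of b
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

infer_element <- function(name) {
  # PDB practice: columns 13-14 hold the element, digits pad small atoms
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  known2 <- c("AR", "KR", "XE", "NE", "HE", "CL", "BR", "NA", "MG", "ZN",
              "FE", "MN", "CA")
  ifelse(two %in% known2 & nchar(nm) == 2, two, substr(nm, 1, 1))
}

resolve_altloc <- function(atom_df) {
  if (!"alt" %in% names(atom_df)) return(atom_df)
  alt <- atom_df$alt
  alt[is.na(alt)] <- ""
  if (!any(nzchar(alt))) return(atom_df)
  key <- paste(atom_df$chain, atom_df$resno, atom_df$insert, atom_df$elety,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atom_df)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- atom_df$o[idx]
    occ[is.na(occ)] <- 0
    best <- idx[occ == max(occ)]
    if (length(best) > 1)  # ties broken by altloc letter order
      best <- best[order(alt[best])][1]
    best[1]
  }), use.names = FALSE)
  atom_df[sort(keep), , drop = FALSE]
}

parse_pdb_header <- function(lines) {
  cell <- NULL
  symops <- NULL
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst)) {
    f <- cryst[1]
    vals <- suppressWarnings(as.numeric(c(
      substr(f, 7, 15), substr(f, 16, 24), substr(f, 25, 33),
      substr(f, 34, 40), substr(f, 41, 47), substr(f, 48, 54))))
    if (!anyNA(vals) && all(vals[1:3] > 0) && !all(vals[1:3] == 1))
      cell <- unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6])
  }
  smtry <- grep("^REMARK 290 +SMTRY[123]", lines, value = TRUE)
  if (!is.null(cell) && length(smtry) >= 3 && length(smtry) %% 3 == 0) {
    nops <- length(smtry) / 3
    symops <- vector("list", nops)
    fracm <- frac_matrix(cell)
    for (k in seq_len(nops)) {
      rows <- smtry[(3 * k - 2):(3 * k)]
      m <- t(vapply(rows, function(r) {
        toks <- strsplit(trimws(sub(".*SMTRY[123]", "", r)),
                         "[[:space:]]+")[[1]]
        suppressWarnings(as.numeric(toks[2:5]))  # token 1 is the op number
      }, numeric(4)))
      if (anyNA(m)) return(list(cell = cell, symops = NULL))
      # SMTRY operators act on Cartesian coordinates; convert to fractional
      symops[[k]] <- symop(fracm %*% m[, 1:3] %*% orth_matrix(cell),
                           as.numeric(fracm %*% m[, 4]))
    }
  }
  list(cell = cell, symops = symops)
}

parse_cif_header <- function(lines) {
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^", tag, "[[:space:]]+"), "", ln[1])))
  }
  cell <- NULL
  a <- grab("_cell.length_a"); b <- grab("_cell.length_b")
  cc <- grab("_cell.length_c")
  if (!anyNA(c(a, b, cc)))
    cell <- unit_cell(a, b, cc,
                      grab("_cell.angle_alpha"), grab("_cell.angle_beta"),
                      grab("_cell.angle_gamma"))
  symops <- NULL
  i <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
            lines)
  if (length(i)) {
    j <- i[length(i)] + 1
    ops <- character(0)
    while (j <= length(lines) && !grepl("^(#|loop_|_)", lines[j]) &&
           nzchar(trimws(lines[j]))) {
      tok <- trimws(lines[j])
      tok <- sub("^[0-9]+[[:space:]]+", "", tok)
      tok <- gsub("'", "", tok)
      ops <- c(ops, gsub("[[:space:]]", "", tok))
      j <- j + 1
    }
    if (length(ops)) symops <- symops_from_strings(ops)
  }
  list(cell = cell, symops = symops)
}

#' Read a coordinate model from PDB or mmCIF
#'
#' All atom records are retained, including heteroatoms (waters, lipid
#' fragments, noble gases). Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by altloc letter). Unit cell and
#' symmetry operators are populated from the header when present.
#'
#' @param path Path to the coordinate file.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", dialect, ": ",
                             conditionMessage(e)))
  at <- resolve_altloc(pdb$atom)
  element <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                   NA, at$elesy)))
  bad <- is.na(element)
  if (any(bad)) {
    warning(sum(bad), " atom(s) lack an element symbol; inferred from name")
    element[bad] <- infer_element(at$elety[bad])
  }
  occ <- at$o
  occ[is.na(occ)] <- 1
  bfac <- at$b
  bfac[is.na(bfac)] <- 0
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = element,
    resname = trimws(at$resid), resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z, occ = occ, b = bfac,
    type = at$type, stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$serial))
    atoms$serial <- seq_len(nrow(atoms))
  lines <- readLines(path, warn = FALSE)
  hdr <- if (dialect == "pdb") parse_pdb_header(lines) else
    parse_cif_header(lines)
  structure_model(atoms, cell = hdr$cell, symops = hdr$symops,
                  label = sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                              ignore.case = TRUE))
}

#' Write a model as a fixed-column PDB file
#'
#' Emits CRYST1 and REMARK 290 SMTRY records when the model carries a cell
#' and symmetry operators, then standard ATOM/HETATM records.
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  out <- character(0)
  if (!is.null(model$cell)) {
    cl <- model$cell
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))
    if (!is.null(model$symops)) {
      orth <- orth_matrix(cl)
      for (k in seq_along(model$symops)) {
        op <- model$symops[[k]]
        tcart <- as.numeric(orth %*% op$translation)
        for (i in 1:3) {
          out <- c(out, sprintf(
            "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
            i, k, op$rotation[i, 1], op$rotation[i, 2], op$rotation[i, 3],
            tcart[i]))
        }
      }
    }
  }
  a <- model$atoms
  fmt_name <- function(nm, el) {
    # element right-justified in cols 13-14 for 1-letter elements
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
           ifelse(nchar(el) == 1 & nchar(nm) <= 3,
                  sprintf(" %-3s", nm), sprintf("%-4s", nm)))
  }
  recs <- sprintf(
    "%-6s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$type == "HETATM", "HETATM", "ATOM"),
    a$serial %% 100000, fmt_name(a$name, a$element),
    substr(a$resname, 1, 3), substr(a$chain, 1, 1), a$resno %% 10000,
    a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(out, recs, "END"), path)
  invisible(path)
}

#' Select a sub-model by composable predicates
#'
#' All supplied predicates are combined by conjunction; atom order and model
#' metadata are preserved. An empty selection is a valid empty model.
#'
#' @param model A [structure_model()].
#' @param protein Keep standard amino-acid residues only.
#' @param ca_only Keep CA atoms of protein residues only.
#' @param element Keep atoms of this element symbol (e.g. `"KR"`).
#' @param chain Keep atoms of this chain identifier.
#' @param hetero Keep HETATM records only.
#' @export
select_atoms <- function(model, protein = FALSE, ca_only = FALSE,
                         element = NULL, chain = NULL, hetero = FALSE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (protein) keep <- keep & a$resname %in% AA3
  if (ca_only) keep <- keep & a$resname %in% AA3 & a$name == "CA"
  if (!is.null(element)) keep <- keep & a$element == toupper(element)
  if (!is.null(chain)) keep <- keep & a$chain == chain
  if (hetero) keep <- keep & a$type == "HETATM"
  structure_model(a[keep, , drop = FALSE], cell = model$cell,
                  symops = model$symops, label = model$label)
}

#' Number of distinct protein residues in a model
#' @param model A [structure_model()].
#' @export
count_protein_residues <- function(model) {
  a <- select_atoms(model, protein = TRUE)$atoms
  length(unique(paste(a$chain, a$resno)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`,
#' constrained to a proper rotation (determinant +1, no reflection).
#'
#' @param mobile,reference N x 3 coordinate matrices, paired by row; N >= 3.
#' @return List with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` best fits `reference`, and the
#'   residual `rmsd` in angstroms.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point sets must have equal length")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 paired points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  h <- t(p) %*% q
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point set: rotation is underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cr - rot %*% cm)
  fitted <- mobile %*% t(rot) + matrix(trans, n, 3, byrow = TRUE)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(sum((fitted - reference)^2) / n))
}

#' Apply a rigid transform to coordinates
#' @param x N x 3 matrix.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector.
#' @export
apply_transform <- function(x, rotation, translation = c(0, 0, 0)) {
  x <- as.matrix(x)
  x %*% t(rotation) + matrix(translation, nrow(x), 3, byrow = TRUE)
}

#' Pair two models atom-by-atom and compute the superposed RMSD
#'
#' Atoms are paired by chain + residue number + atom name over the common
#' set; unmatched atoms are dropped and counted.
#'
#' @param mobile,reference [structure_model()] objects.
#' @param ca_only Restrict the pairing to protein CA atoms.
#' @return List with `rmsd`, `n_pairs`, `n_dropped` and the `transform`.
#' @export
rmsd_structures <- function(mobile, reference, ca_only = TRUE) {
  if (ca_only) {
    mobile <- select_atoms(mobile, ca_only = TRUE)
    reference <- select_atoms(reference, ca_only = TRUE)
  }
  key <- function(a) paste(a$chain, a$resno, a$name, sep = "\r")
  km <- key(mobile$atoms)
  kr <- key(reference$atoms)
  common <- intersect(km, kr)
  n_dropped <- (length(km) - length(common)) + (length(kr) - length(common))
  if (length(common) < 3)
    stop("fewer than 3 atoms could be paired between the models")
  mm <- coords(mobile)[match(common, km), , drop = FALSE]
  rr <- coords(reference)[match(common, kr), , drop = FALSE]
  fit <- superpose(mm, rr)
  if (n_dropped > 0)
    message(n_dropped, " unpaired atom(s) dropped from the RMSD pairing")
  list(rmsd = fit$rmsd, n_pairs = length(common), n_dropped = n_dropped,
       transform = fit)
}

# every (op, lattice shift) image generator; shifts span -1..+1 per axis
symmetry_images <- function(model) {
  if (is.null(model$cell) || is.null(model$symops))
    stop("symmetry expansion requires the model to carry a unit cell and ",
         "symmetry operators; supply them via structure_model()")
  shifts <- as.matrix(expand.grid(sa = -1:1, sb = -1:1, sc = -1:1))
  orth <- orth_matrix(model$cell)
  fracm <- frac_matrix(model$cell)
  fr <- coords(model) %*% t(fracm)
  out <- list()
  for (k in seq_along(model$symops)) {
    op <- model$symops[[k]]
    base <- fr %*% t(op$rotation) +
      matrix(op$translation, nrow(fr), 3, byrow = TRUE)
    for (s in seq_len(nrow(shifts))) {
      if (is_identity_op(op) && all(shifts[s, ] == 0)) next
      imgfr <- base + matrix(shifts[s, ], nrow(fr), 3, byrow = TRUE)
      out[[length(out) + 1]] <- list(op_index = k, shift = shifts[s, ],
                                     xyz = imgfr %*% t(orth))
    }
  }
  out
}

#' Expand crystal symmetry to lattice neighbours within a contact radius
#'
#' Generates every non-identity symmetry image (operator x lattice
#' translations in -1..+1 along each cell axis) that has at least one atom
#' within `radius` of any atom of the central model. Coordinates follow
#' fractionalize -> operate -> orthogonalize.
#'
#' @param model A [structure_model()] carrying cell and symmetry operators.
#' @param radius Contact radius in angstroms (> 0).
#' @return List of images, each a list with `op_index`, `shift`, `model`
#'   (transformed [structure_model()]) and `min_dist` to the central model.
#' @export
symmetry_expand <- function(model, radius) {
  stopifnot(radius > 0)
  xyz0 <- coords(model)
  images <- symmetry_images(model)
  keep <- list()
  for (img in images) {
    # cheap bounding-box rejection before the full distance matrix
    if (any(apply(img$xyz, 2, min) > apply(xyz0, 2, max) + radius) ||
        any(apply(img$xyz, 2, max) < apply(xyz0, 2, min) - radius)) next
    d2 <- cross_dist2(xyz0, img$xyz)
    mind <- sqrt(max(min(d2), 0))
    if (mind < radius) {
      m <- model
      m$atoms$x <- img$xyz[, 1]
      m$atoms$y <- img$xyz[, 2]
      m$atoms$z <- img$xyz[, 3]
      keep[[length(keep) + 1]] <- list(op_index = img$op_index,
                                       shift = img$shift, model = m,
                                       min_dist = mind)
    }
  }
  keep
}

#' Distance from points to the nearest non-identity symmetry image atom
#'
#' @param model A [structure_model()] with cell and symops.
#' @param points M x 3 matrix of query positions (angstroms).
#' @return Numeric vector of length M (Inf where no image exists).
#' @export
nearest_symmetry_contact <- function(model, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  images <- symmetry_images(model)
  best <- rep(Inf, nrow(points))
  for (img in images) {
    d2 <- cross_dist2(points, img$xyz)
    best <- pmin(best, sqrt(pmax(apply(d2, 1, min), 0)))
  }
  best
}
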