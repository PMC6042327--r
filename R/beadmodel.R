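# Coarse-grained bead models: one bead per residue at the CA position, the
# common structural currency for scattering, spin-label and ensemble work.
# All coordinates are nm internally; PDB files on disk are Angstrom (x10).

NM_PER_ANGSTROM <- 0.1

#' Construct a bead model
#'
#' @param beads data frame with columns `protomer` (`"A"`/`"B"`), `resno`
#'   (residue index), `x`, `y`, `z` (nm), `domain` (segment label) and `weight`
#'   (dimensionless scattering weight, default 1).
#' @param provenance optional list (seed, closed flag, ...).
#' @return object of class `bead_model`.
#' @export
bead_model <- function(beads, provenance = list()) {
  beads <- as.data.frame(beads)
  need <- c("protomer", "resno", "x", "y", "z", "domain")
  if (!all(need %in% names(beads))) {
    stop("beads must have columns ", paste(need, collapse = ", "))
  }
  if (!"weight" %in% names(beads)) beads$weight <- 1
  prot <- unique(beads$protomer)
  if (length(prot) == 2) {
    ra <- sort(beads$resno[beads$protomer == prot[1]])
    rb <- sort(beads$resno[beads$protomer == prot[2]])
    if (!identical(ra, rb)) stop("dimer protomers must share residue ranges")
  }
  structure(list(beads = beads, provenance = provenance), class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat("Bead model:", nrow(x$beads), "beads,",
      length(unique(x$beads$protomer)), "protomer(s); Rg =",
      signif(radius_of_gyration(x), 4), "nm\n")
  invisible(x)
}

#' @keywords internal
bm_coords <- function(model, protomer = NULL) {
  b <- model$beads
  if (!is.null(protomer)) b <- b[b$protomer == protomer, , drop = FALSE]
  as.matrix(b[, c("x", "y", "z")])
}

#' Mass-weighted radius of gyration of a bead model (nm)
#'
#' `Rg^2 = sum(w_i |x_i - x_c|^2) / sum(w_i)` with `x_c` the weighted centroid.
#'
#' @param model a [bead_model()] (or a plain coordinate matrix).
#' @param weights optional weights when `model` is a matrix.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(model, weights = NULL) {
  if (inherits(model, "bead_model")) {
    xyz <- bm_coords(model)
    w <- model$beads$weight
  } else {
    xyz <- as.matrix(model)
    w <- weights %||% rep(1, nrow(xyz))
  }
  ctr <- colSums(xyz * w) / sum(w)
  sq <- sweep(xyz, 2, ctr)
  sqrt(sum(w * rowSums(sq^2)) / sum(w))
}

#' Geometric centre of a labelled domain (nm)
#'
#' @param model a [bead_model()].
#' @param domain segment label.
#' @param protomer protomer id.
#' @return length-3 numeric vector.
#' @export
domain_center <- function(model, domain, protomer = "A") {
  b <- model$beads
  sel <- b$domain == domain & b$protomer == protomer
  if (!any(sel)) stop("no beads for domain ", domain, " protomer ", protomer)
  colMeans(as.matrix(b[sel, c("x", "y", "z")]))
}

#' Validate bond-length and clash invariants of a bead model
#'
#' Consecutive beads within a protomer must sit `bond_length` +/- `bond_tol`
#' apart (the CA virtual bond); all other bead pairs must be at least
#' `clash_cutoff` apart.
#'
#' @param model a [bead_model()].
#' @param bond_length,bond_tol,clash_cutoff geometry parameters in nm.
#' @return invisibly TRUE; stops with a message on violation.
#' @export
check_bead_model <- function(model, bond_length = 0.38, bond_tol = 0.01,
                             clash_cutoff = 0.34) {
  b <- model$beads
  for (p in unique(b$protomer)) {
    sub <- b[b$protomer == p, , drop = FALSE]
    sub <- sub[order(sub$resno), , drop = FALSE]
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    d <- sqrt(rowSums(diff(xyz)^2))
    if (any(abs(d - bond_length) > bond_tol)) {
      stop("bond-length violation in protomer ", p, ": range [",
           signif(min(d), 4), ", ", signif(max(d), 4), "] nm")
    }
  }
  xyz <- bm_coords(model)
  dm <- as.matrix(stats::dist(xyz))
  # mask consecutive residues within the same protomer
  same <- outer(model$beads$protomer, model$beads$protomer, "==")
  adj <- abs(outer(model$beads$resno, model$beads$resno, "-")) == 1
  dm[same & adj] <- Inf
  diag(dm) <- Inf
  if (min(dm) < clash_cutoff) {
    stop("clash: minimum non-adjacent distance ", signif(min(dm), 4), " nm")
  }
  invisible(TRUE)
}

# ---- PDB + pool I/O -------------------------------------------------------

#' Write a bead model as a CA-only PDB file
#'
#' Coordinates are converted from nm to Angstrom on disk (factor 10); chains A
#' and B hold the two protomers; the scattering weight is stored in the
#' B-factor column.
#'
#' @param model a [bead_model()].
#' @param path output file.
#' @export
write_beadmodel_pdb <- function(model, path) {
  b <- model$beads
  b <- b[order(b$protomer, b$resno), , drop = FALSE]
  xyz <- as.numeric(t(as.matrix(b[, c("x", "y", "z")]) / NM_PER_ANGSTROM))
  bio3d::write.pdb(file = path, xyz = xyz, resno = b$resno,
                   resid = rep("ALA", nrow(b)), chain = b$protomer,
                   elety = rep("CA", nrow(b)), o = rep(1, nrow(b)),
                   b = b$weight)
  invisible(path)
}

#' Read a CA-only PDB file back into a bead model
#'
#' @param path PDB file written by [write_beadmodel_pdb()] (or any CA trace).
#' @param arch optional [domain_architecture()] used to restore domain labels.
#' @return a [bead_model()].
#' @export
read_beadmodel_pdb <- function(path, arch = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  beads <- data.frame(
    protomer = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    x = at$x * NM_PER_ANGSTROM, y = at$y * NM_PER_ANGSTROM,
    z = at$z * NM_PER_ANGSTROM,
    domain = NA_character_, weight = ifelse(is.na(at$b), 1, at$b),
    stringsAsFactors = FALSE
  )
  if (!is.null(arch)) {
    segs <- arch$segments
    for (i in seq_len(nrow(segs))) {
      hit <- beads$resno >= segs$start[i] & beads$resno <= segs$end[i] &
        is.na(beads$domain)
      beads$domain[hit] <- segs$name[i]
    }
  }
  bead_model(beads)
}

#' Write a conformer pool to disk
#'
#' One CA-only PDB per conformer plus a TSV manifest (index, Rg, closed flag,
#' per-conformer seed).
#'
#' @param pool a `conformer_pool` from [generate_pool()].
#' @param dir output directory (created if needed).
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(pool$conformers)
  files <- sprintf("conformer_%04d.pdb", seq_len(n))
  for (i in seq_len(n)) {
    write_beadmodel_pdb(pool$conformers[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    index = seq_len(n), file = files, rg_nm = pool$rg,
    closed = pool$closed,
    seed = vapply(pool$conformers, function(m) m$provenance$seed, numeric(1))
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a conformer pool written by [write_pool()]
#'
#' @param dir pool directory.
#' @param arch optional architecture for domain labels.
#' @return a `conformer_pool`.
#' @export
read_pool <- function(dir, arch = NULL) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  conformers <- lapply(manifest$file, function(f) {
    read_beadmodel_pdb(file.path(dir, f), arch = arch)
  })
  structure(list(conformers = conformers, rg = manifest$rg_nm,
                 closed = manifest$closed, seed = NA_integer_),
            class = "conformer_pool")
}
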