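#' Rigid-body transform
#'
#' A proper rigid motion `y = R x + t` together with the RMSD of the fit
#' that produced it. The rotation is always orthonormal with determinant +1
#' (reflections are excluded by construction in [kabsch_fit()]).
#'
#' @param rotation 3 x 3 matrix
#' @param translation length-3 vector, Angstrom
#' @param rmsd RMSD of the fitted pairing, Angstrom
#' @param n_atoms number of fitted pairs
#' @return object of class `Transform`
#' @export
rigid_transform <- function(rotation, translation, rmsd = NA_real_,
                      n_atoms = NA_integer_) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation determinant is not +1 (improper rotation)")
  }
  if (!is.na(rmsd) && rmsd < 0) stop("negative rmsd")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 rmsd = rmsd, n_atoms = n_atoms),
            class = "Transform")
}

#' @export
print.Transform <- function(x, ...) {
  cat(sprintf("Transform: rmsd = %.4g A over %s atoms\n",
              x$rmsd, format(x$n_atoms)))
  invisible(x)
}

#' Identity transform
#' @return Transform with identity rotation and zero translation
#' @export
identity_transform <- function() {
  rigid_transform(diag(3), c(0, 0, 0), 0, NA_integer_)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rigid motion minimizing the RMSD of `mobile` onto
#' `reference` over paired rows, via SVD of the covariance matrix with the
#' standard sign correction that excludes reflections.
#'
#' @param mobile,reference n x 3 matrices of paired coordinates, n >= 3
#' @return [rigid_transform()] whose rotation/translation map mobile onto
#'   reference, with the residual RMSD of the fit
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) stop("paired sets differ in shape")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 paired atoms are required")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  x <- sweep(mobile, 2, mc); y <- sweep(reference, 2, rc)
  h <- crossprod(x, y)                    # 3x3 covariance
  s <- svd(h)
  if (s$d[2L] < 1e-12 * max(s$d[1L], 1)) {
    stop("degenerate (collinear) point configuration; cannot fit rotation")
  }
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rc - as.numeric(rot %*% mc)
  fitted <- x %*% t(rot)
  rmsd <- sqrt(sum((fitted - y)^2) / n)
  rigid_transform(rot, tr, rmsd = rmsd, n_atoms = n)
}

#' Apply a transform to coordinates
#' @param t Transform
#' @param coords n x 3 matrix
#' @return n x 3 matrix of `R x + t` applied rowwise
#' @export
apply_transform <- function(t, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be n x 3")
  out <- coords %*% t(t$rotation)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  out[, 3] <- out[, 3] + t$translation[3]
  dimnames(out) <- dimnames(coords)
  out
}

#' Invert a transform
#' @param t Transform
#' @return Transform undoing `t`
#' @export
invert_transform <- function(t) {
  rinv <- t(t$rotation)
  rigid_transform(rinv, -as.numeric(rinv %*% t$translation), t$rmsd, t$n_atoms)
}

#' Apply a transform to every atom of a model
#' @param model StructureModel
#' @param t Transform
#' @return transformed StructureModel
#' @export
transform_model <- function(model, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- apply_transform(t, xyz)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Serialize a transform to a JSON-ready list
#' @param t Transform
#' @return list with row-major rotation, translation, rmsd, n_atoms
#' @export
transform_to_list <- function(t) {
  list(rotation = as.numeric(t(t$rotation)), translation = t$translation,
       rmsd = t$rmsd, n_atoms = t$n_atoms)
}

#' Core-based superposition of two models
#'
#' Implements the domain-comparison convention used throughout this
#' package: each chain of the mobile model is fitted onto its paired
#' reference chain using only the backbone atoms (N, CA, C, O) of the
#' configured core segments (central beta-strands plus the helix following
#' the catalytic Ser). Localized loop motions then become measurable in the
#' common reference frame. Fitting is per chain because shift and triangle
#' statistics are reported per monomer and then averaged.
#'
#' @param mobile,reference StructureModels
#' @param core list of segment specs (`chain`, `start`, `end`) expressed in
#'   reference chain ids/numbering
#' @param chain_pairing `"by_id"` (default), or a named character vector
#'   mapping reference chain id -> mobile chain id
#' @param atoms backbone atom names used for the fit
#' @return list with `transforms` (named per reference chain), `rmsd`
#'   (named numeric), and `model` (the transformed mobile copy)
#' @export
core_superpose <- function(mobile, reference, core,
                           chain_pairing = "by_id",
                           atoms = c("N", "CA", "C", "O")) {
  core_chains <- unique(vapply(core, `[[`, character(1), "chain"))
  if (identical(chain_pairing, "by_id")) {
    pairing <- setNames(core_chains, core_chains)
  } else {
    pairing <- chain_pairing
    unmatched <- setdiff(core_chains, names(pairing))
    if (length(unmatched) > 0L) {
      stop("no mobile chain paired with reference chain(s): ",
           paste(unmatched, collapse = ", "))
    }
  }
  out_model <- mobile
  transforms <- list(); rmsds <- numeric(0)
  for (ref_ch in core_chains) {
    mob_ch <- pairing[[ref_ch]]
    if (!(mob_ch %in% model_chains(mobile))) {
      stop("mobile model '", mobile$id, "' has no chain '", mob_ch, "'")
    }
    segs <- Filter(function(s) s$chain == ref_ch, core)
    sel_ref <- expand_segments(reference, segs, atoms = atoms)
    sel_mob <- atom_selection(mob_ch, sel_ref$resseq, sel_ref$atom,
                              sel_ref$icode)
    xyz_ref <- select_atoms(reference, sel_ref, strict = TRUE)
    xyz_mob <- select_atoms(mobile, sel_mob, strict = TRUE)
    tr <- kabsch_fit(xyz_mob, xyz_ref)
    transforms[[ref_ch]] <- tr
    rmsds[ref_ch] <- tr$rmsd
    # move every atom of the paired mobile chain into the reference frame
    idx <- out_model$atoms$chain == mob_ch
    xyz <- as.matrix(out_model$atoms[idx, c("x", "y", "z")])
    xyz <- apply_transform(tr, xyz)
    out_model$atoms$x[idx] <- xyz[, 1]
    out_model$atoms$y[idx] <- xyz[, 2]
    out_model$atoms$z[idx] <- xyz[, 3]
  }
  list(transforms = transforms, rmsd = rmsds, model = out_model,
       pairing = pairing)
}
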