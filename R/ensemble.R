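#' Conformational ensemble
#'
#' An ordered list of conformations sharing one atom topology (same chains,
#' residues and atom names), e.g. snapshots of a trajectory or the models
#' of a multi-model PDB file.
#'
#' @param frames list of StructureModels
#' @param labels frame labels (default frame index)
#' @return object of class `Ensemble`
#' @export
as_ensemble <- function(frames, labels = NULL) {
  if (length(frames) < 1L) stop("an ensemble needs at least one frame")
  sig <- function(m) paste(m$atoms$chain, m$atoms$resseq, m$atoms$icode,
                           m$atoms$atom, collapse = "|")
  s0 <- sig(frames[[1L]])
  for (i in seq_along(frames)[-1L]) {
    if (!identical(sig(frames[[i]]), s0)) {
      stop("frame ", i, " does not share the topology of frame 1")
    }
  }
  if (is.null(labels)) labels <- as.character(seq_along(frames))
  structure(list(frames = frames, labels = labels), class = "Ensemble")
}

#' Read an ensemble from a multi-model PDB file or several files
#' @param paths one multi-model PDB path, or a vector of single-model paths
#' @return Ensemble
#' @export
read_ensemble <- function(paths) {
  if (length(paths) == 1L) {
    frames <- parse_structure(paths, ensemble = TRUE)
    if (inherits(frames, "StructureModel")) frames <- list(frames)
  } else {
    frames <- lapply(paths, parse_structure)
  }
  as_ensemble(frames)
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d frames, %d atoms each\n", length(x$frames),
              nrow(x$frames[[1L]]$atoms)))
  invisible(x)
}

#' Clustering parameters
#'
#' @param cutoff RMSD cutoff in Angstrom (default 1.0)
#' @param atoms atom names of the clustering selection (default main-chain
#'   plus C-beta)
#' @param fit_before_distance superpose each frame pair before the RMSD
#'   (default TRUE)
#' @return list of class `ClusteringParams`
#' @export
clustering_params <- function(cutoff = 1.0,
                              atoms = c("N", "CA", "C", "O", "CB"),
                              fit_before_distance = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff, atoms = atoms,
                 fit_before_distance = fit_before_distance),
            class = "ClusteringParams")
}

.ensemble_selection <- function(ensemble, atoms) {
  a <- ensemble$frames[[1L]]$atoms
  keep <- a$atom %in% atoms & !a$het & !a$water & !a$hydrogen
  if (!any(keep)) stop("clustering selection resolves no atoms")
  atom_selection(a$chain[keep], a$resseq[keep], a$atom[keep], a$icode[keep])
}

#' Pairwise RMSD matrix over an ensemble
#'
#' Entry (i, j) is the RMSD between frames i and j over the clustering
#' selection, after optimal rigid superposition of frame j onto frame i
#' when `fit_before_distance` is set. The matrix is symmetric with a zero
#' diagonal.
#'
#' @param ensemble Ensemble
#' @param params [clustering_params()]
#' @return n x n symmetric numeric matrix, Angstrom
#' @export
pairwise_rmsd_matrix <- function(ensemble, params = clustering_params()) {
  n <- length(ensemble$frames)
  if (n < 2L) stop("at least 2 frames required")
  sel <- .ensemble_selection(ensemble, params$atoms)
  coords <- lapply(seq_len(n), function(i) {
    tryCatch(select_atoms(ensemble$frames[[i]], sel, strict = TRUE),
             error = function(e) stop("frame ", i, ": ", conditionMessage(e)))
  })
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (params$fit_before_distance) {
        r <- kabsch_fit(coords[[j]], coords[[i]])$rmsd
      } else {
        r <- sqrt(sum((coords[[j]] - coords[[i]])^2) / nrow(coords[[i]]))
      }
      m[i, j] <- r; m[j, i] <- r
    }
  }
  m
}

#' GROMOS-style neighbor-counting clustering
#'
#' Iteratively takes the frame with the most neighbors within the cutoff
#' (ties broken by the lowest frame index), forms a cluster of it plus its
#' neighbors, removes them, and repeats until every frame is assigned. The
#' seed frame of each cluster is its representative, so every member lies
#' within the cutoff of its cluster's representative by construction.
#' Clusters are numbered by decreasing size (ties by formation order).
#'
#' @param matrix square symmetric pairwise RMSD matrix with zero diagonal
#' @param cutoff neighbor cutoff in Angstrom
#' @return object of class `ClusteringResult`: `assignment` (frame ->
#'   cluster id), `representative` (frame index per cluster), `size`,
#'   `fraction`
#' @export
gromos_cluster <- function(matrix, cutoff = 1.0) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (ncol(m) != n) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix must be symmetric")
  if (max(abs(diag(m))) > 1e-9) stop("matrix must have zero diagonal")
  remaining <- rep(TRUE, n)
  assignment <- integer(n)
  reps <- integer(0); sizes <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- vapply(idx, function(i) {
      sum(m[i, idx] <= cutoff) - 1L
    }, integer(1))
    seed <- idx[which.max(counts)]   # which.max takes the lowest on ties
    members <- idx[m[seed, idx] <= cutoff]
    cl <- cl + 1L
    assignment[members] <- cl
    reps[cl] <- seed
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  ord <- order(-sizes, seq_along(sizes))
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  structure(list(assignment = relabel[assignment],
                 representative = reps[ord],
                 size = sizes[ord],
                 fraction = sizes[ord] / n,
                 cutoff = cutoff),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: %d clusters (cutoff %.2f A)\n",
              length(x$size), x$cutoff))
  for (i in seq_along(x$size)) {
    cat(sprintf("  #%d: %d frames (%.1f%%), representative frame %d\n",
                i, x$size[i], 100 * x$fraction[i], x$representative[i]))
  }
  invisible(x)
}

#' Catalytic-Ser sidechain SASA over an ensemble
#'
#' One value per frame via [ser_sidechain_sasa()], frame order preserved.
#'
#' @param ensemble Ensemble
#' @param site SiteDefinition
#' @param params [sasa_params()]
#' @param chain passed through to [ser_sidechain_sasa()]
#' @return numeric vector, Angstrom^2
#' @export
sasa_series <- function(ensemble, site, params = sasa_params(),
                        chain = NULL) {
  vapply(ensemble$frames, function(f) {
    ser_sidechain_sasa(f, site, params = params, chain = chain)
  }, numeric(1))
}

#' Two-component Gaussian mixture fit (EM)
#'
#' Maximum-likelihood univariate two-normal mixture fitted by
#' expectation-maximization. Initialization is deterministic (split at the
#' median), so the fit needs no random seed; convergence when the
#' log-likelihood improves by less than `tol` or after `max_iter`
#' iterations. Component means are reported in ascending order. A fit
#' whose means differ by less than the larger fitted sigma is flagged
#' near-degenerate (a single-component summary is then more honest).
#'
#' @param values numeric vector, at least 50 values
#' @param init optional list with `mean`, `sigma`, `weight` (each length 2)
#' @param tol log-likelihood convergence tolerance (default 1e-8)
#' @param max_iter maximum EM iterations (default 500)
#' @return object of class `GaussianMixtureFit`: `mean`, `sigma`, `weight`
#'   (ascending-mean order), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `degenerate`
#' @export
fit_two_gaussians <- function(values, init = NULL, tol = 1e-8,
                              max_iter = 500L) {
  x <- as.numeric(values)
  if (length(x) < 50L) stop("at least 50 values required for a mixture fit")
  if (sd(x) < 1e-12) {
    stop("degenerate data (zero variance); report a single-component summary")
  }
  if (is.null(init)) {
    med <- stats::median(x)
    lo <- x[x <= med]; hi <- x[x > med]
    if (length(hi) == 0L) { hi <- lo }  # heavy ties at the median
    mu <- c(mean(lo), mean(hi))
    sg <- pmax(c(sd(lo), sd(hi)), sd(x) / 100, 1e-8)
    sg[is.na(sg)] <- sd(x) / 2
    w <- c(length(lo), length(hi)) / length(x)
    w <- pmin(pmax(w, 1e-3), 1 - 1e-3); w <- w / sum(w)
  } else {
    mu <- init$mean; sg <- init$sigma; w <- init$weight
  }
  sigma_floor <- sd(x) * 1e-6
  loglik_trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(x) - n1
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sg <- c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
            sqrt(sum((1 - g1) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, sigma_floor)
    w <- c(n1, n2) / length(x)
  }
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  structure(list(mean = mu, sigma = sg, weight = w,
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace,
                 n_iter = it, converged = converged,
                 degenerate = abs(diff(mu)) < max(sg)),
            class = "GaussianMixtureFit")
}

#' @export
print.GaussianMixtureFit <- function(x, ...) {
  cat(sprintf(
    "GaussianMixtureFit: mu = %.2f / %.2f, sigma = %.2f / %.2f, w = %.2f / %.2f%s\n",
    x$mean[1], x$mean[2], x$sigma[1], x$sigma[2], x$weight[1], x$weight[2],
    if (x$degenerate) " [near-degenerate]" else ""))
  invisible(x)
}
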