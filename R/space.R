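#' Principal coordinates embedding of a distance matrix
#'
#' Classical scaling (Torgerson): the squared distances are double-centred,
#' the Gram matrix eigendecomposed, and axes with positive eigenvalues
#' retained with coordinates scaled by the square root of the eigenvalue.
#' Negative-eigenvalue axes (non-Euclidean residual) are dropped and their
#' total magnitude reported; no Cailliez/Lingoes correction is applied.
#'
#' @param dm a [stats::dist] object (or symmetric matrix) with labels.
#' @return list with `coords` (matrix, rows labelled), `eigenvalues` (all,
#'   decreasing), `negative_mass` (sum of |negative eigenvalues|).
#' @export
pcoa_embed <- function(dm) {
  if (is.matrix(dm)) {
    if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
      stop("distance matrix is not symmetric")
    dm <- stats::as.dist(dm)
  }
  n <- attr(dm, "Size")
  fit <- suppressWarnings(cmdscale(dm, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  npos <- sum(eig > tol)
  if (npos == 0L)
    return(list(coords = matrix(0, n, 0,
                                dimnames = list(attr(dm, "Labels"), NULL)),
                eigenvalues = eig, negative_mass = sum(abs(eig[eig < 0]))))
  coords <- fit$points[, seq_len(npos), drop = FALSE]
  rownames(coords) <- attr(dm, "Labels")
  colnames(coords) <- paste0("PCoA", seq_len(npos))
  list(coords = coords, eigenvalues = eig,
       negative_mass = sum(abs(eig[eig < 0])))
}

#' Embedding quality: mean squared deviation (mSD)
#'
#' Both the initial distances and the Euclidean distances in the reduced
#' space are rescaled to `[0, 1]` by their own maxima; the mSD is the mean
#' over unordered pairs of the squared deviation between the two rescaled
#' distances. 0 means the embedding reproduces the initial distances up to
#' a global scale factor.
#'
#' @param dm initial distance matrix ([stats::dist]) with labels.
#' @param coords coordinates on the retained axes, rows labelled
#'   consistently with `dm`.
#' @return the mSD value.
#' @export
msd_quality <- function(dm, coords) {
  labs <- attr(dm, "Labels")
  if (is.null(rownames(coords)) || !setequal(labs, rownames(coords)) ||
      length(labs) != nrow(coords))
    stop("coordinate labels do not match the distance matrix")
  coords <- coords[labs, , drop = FALSE]
  d0 <- as.vector(dm)
  d1 <- as.vector(dist(coords))
  if (max(d0) == 0) stop("all initial distances are zero")
  d0 <- d0 / max(d0)
  if (max(d1) > 0) d1 <- d1 / max(d1)
  mean((d0 - d1)^2)
}

#' Build a functional space from a trait table
#'
#' Species are collapsed into functional entities, Gower distances among
#' FE trait vectors are embedded by principal coordinates, and the first
#' `d` axes (default 4) are retained with the mSD quality index.
#'
#' @param table validated species-by-trait table.
#' @param schema the `trait_schema`.
#' @param d number of axes to keep (>= 2).
#' @param ordinal ordinal convention passed to [gower_dist()].
#' @return an object of class `functional_space`: list with `labels` (FE
#'   ids), `coords` (FE-by-`d` matrix), `eigenvalues`, `n_axes`, `msd`,
#'   `negative_mass`, `partition` (the `fe_partition`), `config`.
#' @export
build_space <- function(table, schema, d = 4L,
                        ordinal = c("rank", "nominal", "podani")) {
  ordinal <- match.arg(ordinal)
  if (d < 2L) stop("need at least 2 axes")
  partition <- build_functional_entities(table, schema)
  if (n_fe(partition) < d + 1L)
    stop("need at least d+1 = ", d + 1L, " functional entities")
  dm <- gower_dist(partition$fe_table, schema, ordinal = ordinal)
  emb <- pcoa_embed(dm)
  if (ncol(emb$coords) < d)
    stop("only ", ncol(emb$coords), " positive-eigenvalue axes; ",
         "use a smaller d")
  coords <- emb$coords[, seq_len(d), drop = FALSE]
  structure(list(labels = rownames(coords), coords = coords,
                 eigenvalues = emb$eigenvalues, n_axes = d,
                 msd = msd_quality(dm, coords),
                 negative_mass = emb$negative_mass,
                 partition = partition,
                 config = list(ordinal = ordinal, d = d)),
            class = "functional_space")
}

#' Build a functional space directly from a distance matrix
#'
#' Lower-level companion to [build_space()] for pre-computed distances
#' (entities need not be FEs).
#'
#' @param dm a labelled [stats::dist].
#' @param d number of axes to keep.
#' @return a `functional_space` (without a `partition`).
#' @export
space_from_dist <- function(dm, d = 4L) {
  emb <- pcoa_embed(dm)
  if (ncol(emb$coords) < d)
    stop("only ", ncol(emb$coords), " positive-eigenvalue axes; ",
         "use a smaller d")
  coords <- emb$coords[, seq_len(d), drop = FALSE]
  structure(list(labels = rownames(coords), coords = coords,
                 eigenvalues = emb$eigenvalues, n_axes = d,
                 msd = msd_quality(dm, coords),
                 negative_mass = emb$negative_mass,
                 partition = NULL, config = list(d = d)),
            class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat("Functional space:", length(x$labels), "entities on", x$n_axes,
      "PCoA axes\n")
  cat(sprintf("  mSD = %.4g | dropped negative-eigenvalue mass = %.3g\n",
              x$msd, x$negative_mass))
  invisible(x)
}
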