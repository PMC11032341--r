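# Representational dissimilarity matrices. Raw pairwise dissimilarities
# between per-stimulus activation vectors are rank-transformed onto [0, 1]
# (average ranks for ties), which makes the matrix invariant to any
# strictly increasing reparameterization of the raw distance.

# Flatten activations to an (n_stimuli x features) matrix.
.acts_to_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  .assert(is.array(x) && length(dim(x)) == 4,
          "activations must be a matrix or (image, filter, y, x) array")
  matrix(x, nrow = dim(x)[1])
}

#' Compute a rank-normalized dissimilarity matrix
#'
#' Per stimulus, activations are flattened to one vector; the raw
#' dissimilarity between two stimuli is `1 - r` (product-moment correlation,
#' the default) or the Euclidean distance. Off-diagonal values are then
#' rank-transformed: ranks (average over ties) are mapped onto \[0, 1\] via
#' `(rank - 1) / (n_pairs - 1)`. Stimuli whose activation vector has zero
#' variance (undefined correlation) are flagged and excluded, shrinking the
#' matrix.
#'
#' @param activations (image x filter x y x x) array (e.g. from
#'   [layer_activations()]) or an (image x features) matrix.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param provenance optional free-form provenance list stored on the result.
#' @return object of class `rdm`: `values` (symmetric matrix, zero diagonal,
#'   off-diagonal in \[0,1\]), `n_stimuli`, `excluded` (indices dropped),
#'   `distance`, `provenance`.
#' @export
compute_rdm <- function(activations, distance = c("correlation", "euclidean"),
                        provenance = NULL) {
  distance <- match.arg(distance)
  m <- .acts_to_matrix(activations)
  .assert(nrow(m) >= 3, "need at least 3 stimuli")
  .assert(ncol(m) >= 2, "need at least 2 features (filters x positions)")
  excluded <- integer(0)
  if (distance == "correlation") {
    sds <- apply(m, 1, stats::sd)
    excluded <- which(sds == 0)
    if (length(excluded) > 0) {
      warning(sprintf("%d stimulus(es) with zero-variance activations excluded",
                      length(excluded)))
      m <- m[-excluded, , drop = FALSE]
      .assert(nrow(m) >= 3, "fewer than 3 stimuli left after exclusion")
    }
    raw <- 1 - stats::cor(t(m))
  } else {
    raw <- as.matrix(stats::dist(m))
  }
  n <- nrow(raw)
  lower <- raw[lower.tri(raw)]
  rk <- rank(lower, ties.method = "average")
  norm <- if (length(lower) > 1) (rk - 1) / (length(lower) - 1) else
    rep(0, length(lower))
  values <- matrix(0, n, n)
  values[lower.tri(values)] <- norm
  values <- values + t(values)
  structure(list(values = values, n_stimuli = n, excluded = excluded,
                 distance = distance, provenance = provenance),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm %d stimuli (%s distance)%s>\n", x$n_stimuli, x$distance,
              if (length(x$excluded)) sprintf(", %d excluded",
                                              length(x$excluded)) else ""))
  invisible(x)
}

.rdm_lower <- function(x) {
  v <- if (inherits(x, "rdm")) x$values else x
  v[lower.tri(v)]
}

#' Correlation between two dissimilarity matrices
#'
#' Product-moment correlation over the vectorized lower triangles
#' (diagonal excluded). On rank-normalized entries this equals a rank
#' correlation of the raw distances up to tie effects.
#'
#' @param a,b `rdm` objects (or plain symmetric matrices) over the same
#'   stimuli in the same order.
#' @return correlation in \[-1, 1\].
#' @export
rdm_correlation <- function(a, b) {
  va <- .rdm_lower(a); vb <- .rdm_lower(b)
  .assert(length(va) == length(vb),
          "dissimilarity matrices are over different stimulus sets")
  stats::cor(va, vb)
}

#' Split-half reliability of a representation
#'
#' Filters are randomly partitioned into two near-equal groups; an RDM is
#' computed from each group and correlated; the mean over `n_splits` random
#' splits is returned. This is the within-(layer, stream) reference value
#' against which between-stream RDM correlations are read.
#'
#' @param activations (image x filter x y x x) array, or (image x filter)
#'   matrix (one feature per filter).
#' @param n_splits number of random splits (default 10).
#' @param seed integer seed.
#' @param distance passed to [compute_rdm()].
#' @return mean correlation across splits (attribute `"splits"` carries the
#'   per-split values).
#' @export
split_half_reliability <- function(activations, n_splits = 10, seed = 1,
                                   distance = "correlation") {
  x <- activations
  if (is.matrix(x)) dim(x) <- c(dim(x), 1, 1)
  .assert(length(dim(x)) == 4, "activations must be 4-D or a matrix")
  nf <- dim(x)[2]
  .assert(nf >= 4, "need at least 4 filters for split-half reliability")
  rs <- .with_seed(seed, vapply(seq_len(n_splits), function(i) {
    g1 <- sort(sample(nf, nf %/% 2))
    g2 <- setdiff(seq_len(nf), g1)
    r1 <- compute_rdm(x[, g1, , , drop = FALSE], distance = distance)
    r2 <- compute_rdm(x[, g2, , , drop = FALSE], distance = distance)
    rdm_correlation(r1, r2)
  }, numeric(1)))
  structure(mean(rs), splits = rs)
}

#' Cross-layer, cross-stream RDM correlation table
#'
#' Computes an RDM for every (layer, stream) of the model on a fixed
#' stimulus set and correlates all pairs. Same-(layer, stream) entries use
#' [split_half_reliability()] instead of the trivial self-correlation.
#'
#' @param model a trained `stream_net`.
#' @param stimuli (H, W, 3, N) array or a stimulus set from
#'   [generate_rdm_stimulus_set()].
#' @param layers layer names (default all conv layers).
#' @param n_splits splits for the diagonal reliability entries.
#' @param seed seed for the random splits.
#' @param distance passed to [compute_rdm()].
#' @return data.frame with columns `layer_a`, `stream_a`, `layer_b`,
#'   `stream_b`, `r`, `type` (`"cross"` or `"split_half"`).
#' @export
cross_layer_matrix <- function(model, stimuli, layers = NULL, n_splits = 10,
                               seed = 1, distance = "correlation") {
  net <- .resolve_net(model)
  model <- net$model
  if (is.list(stimuli) && !is.null(stimuli$x)) stimuli <- stimuli$x
  if (is.null(layers)) {
    layers <- paste0("conv", seq_along(model$arch$conv_layers))
  }
  combos <- expand.grid(layer = layers,
                        stream = seq_len(model$arch$n_streams),
                        stringsAsFactors = FALSE)
  acts <- vector("list", nrow(combos))
  rdms <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    acts[[i]] <- layer_activations(model, stimuli, combos$layer[i],
                                   combos$stream[i])
    rdms[[i]] <- compute_rdm(acts[[i]], distance = distance,
                             provenance = list(layer = combos$layer[i],
                                               stream = combos$stream[i]))
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    for (j in i:nrow(combos)) {
      if (i == j) {
        r <- as.numeric(split_half_reliability(acts[[i]], n_splits = n_splits,
                                               seed = seed,
                                               distance = distance))
        type <- "split_half"
      } else {
        r <- rdm_correlation(rdms[[i]], rdms[[j]])
        type <- "cross"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(layer_a = combos$layer[i], stream_a = combos$stream[i],
                   layer_b = combos$layer[j], stream_b = combos$stream[j],
                   r = r, type = type, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Between-stream RDM correlation per layer
#'
#' Convenience extraction: the correlation between the two streams' RDMs at
#' each hierarchical level (for 2-stream models).
#'
#' @param cross_table output of [cross_layer_matrix()].
#' @return data.frame with `layer` and `r`.
#' @export
between_stream_rdm <- function(cross_table) {
  sel <- cross_table$layer_a == cross_table$layer_b &
    cross_table$stream_a != cross_table$stream_b
  out <- cross_table[sel, c("layer_a", "r")]
  names(out) <- c("layer", "r")
  rownames(out) <- NULL
  out
}
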