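#' Partition T1 values into bins by 1-D clustering
#'
#' Bins let the estimated confounder bias depend on the T1 value itself
#' (higher T1 values may be affected differently than lower ones). Pooled
#' segmented training values are clustered by one of eight algorithms; the
#' resulting 1-D clusters are converted to contiguous half-open intervals
#' `[lo, hi)` whose boundaries are midpoints between adjacent clusters'
#' extreme members, extended to -Inf/+Inf at the ends so that assignment is
#' total. A value equal to a boundary falls into the upper bin.
#'
#' For `equal_distant` all bins have the same width (boundaries at
#' `min + k * (max - min) / n_bins`); for `equal_size` the values are sorted
#' and split into bins of (as near as possible) equal occupancy. The
#' agglomerative variants and the equal_* rules are deterministic; k-means
#' and the Gaussian mixture are seeded.
#'
#' @param values Numeric vector of T1 values (ms), length >= `n_bins`.
#' @param n_bins Number of bins (>= 1). More than 10 bins triggers a warning
#'   (per-bin occupancy becomes unrepresentative) but proceeds.
#' @param cluster_type One of `"agglomerative_average"`,
#'   `"agglomerative_complete"`, `"agglomerative_single"`,
#'   `"agglomerative_ward"`, `"equal_distant"`, `"equal_size"`,
#'   `"gaussian_mixture"`, `"k_means"`.
#' @param seed Integer seed for the stochastic cluster types.
#' @return A `bin_partition` object with interior `breaks` (sorted numeric
#'   vector of length `n_bins - 1`).
#' @export
#' @examples
#' p <- fit_partition(c(1000, 1010, 1090, 1100), 2, "equal_distant")
#' assign_bin(p, c(1049, 1050))
fit_partition <- function(values, n_bins, cluster_type = cluster_types(), seed = 1L) {
  cluster_type <- match.arg(cluster_type)
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) abort_input("values must be nonempty and free of NA")
  if (!is_scalar_number(n_bins) || n_bins < 1) abort_config("n_bins must be an integer >= 1")
  n_bins <- as.integer(n_bins)
  if (n_bins > length(values)) {
    abort_config(paste0("n_bins (", n_bins, ") exceeds the number of values (", length(values), ")"))
  }
  if (n_bins > 10L) {
    warning("more than 10 bins requested; per-bin occupancy may be unrepresentative", call. = FALSE)
  }
  if (n_bins == 1L) {
    return(new_bin_partition(1L, cluster_type, numeric(0), seed))
  }
  if (length(unique(values)) == 1L) {
    abort_config("all values are identical; clusters into more than one bin are undefined")
  }

  breaks <- switch(
    cluster_type,
    equal_distant = {
      rng <- range(values)
      rng[1] + seq_len(n_bins - 1L) * diff(rng) / n_bins
    },
    equal_size = {
      s <- sort(values)
      sizes <- rep(length(s) %/% n_bins, n_bins)
      extra <- length(s) %% n_bins
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      cut_idx <- cumsum(sizes)[-n_bins]
      (s[cut_idx] + s[cut_idx + 1L]) / 2
    },
    {
      cl <- cluster_assignments_1d(values, n_bins, cluster_type, seed)
      boundaries_from_clusters(values, cl)
    }
  )
  breaks <- sort(unique(breaks))
  if (length(breaks) != n_bins - 1L) {
    abort_config(paste0("could not derive ", n_bins, " distinct bins with ", cluster_type,
                        " clustering on these values"))
  }
  new_bin_partition(n_bins, cluster_type, breaks, seed)
}

cluster_assignments_1d <- function(values, k, cluster_type, seed) {
  if (startsWith(cluster_type, "agglomerative_")) {
    method <- switch(sub("^agglomerative_", "", cluster_type),
                     average = "average", complete = "complete",
                     single = "single", ward = "ward.D2")
    h <- stats::hclust(stats::dist(values), method = method)
    return(stats::cutree(h, k = k))
  }
  if (cluster_type == "k_means") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(values, centers = k, nstart = 10L)
    return(km$cluster)
  }
  if (cluster_type == "gaussian_mixture") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    # Mclust evaluates its BIC call in the caller's frame; make the helper
    # visible there
    mclustBIC <- mclust::mclustBIC
    fit <- tryCatch(
      mclust::Mclust(values, G = k, modelNames = c("V", "E"), verbose = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit)) abort_config("gaussian mixture fit failed on these values")
    return(fit$classification)
  }
  abort_config(paste0("unknown cluster type: ", cluster_type))
}

# convert arbitrary 1-D cluster labels to interval boundaries: order clusters
# by mean, boundary = midpoint between the extreme members of adjacent
# clusters (non-contiguous labelings collapse to this contiguous reading)
boundaries_from_clusters <- function(values, cl) {
  means <- tapply(values, cl, mean)
  ord <- names(sort(means))
  lo_hi <- vapply(ord, function(g) range(values[cl == g]), numeric(2))
  k <- length(ord)
  vapply(seq_len(k - 1L), function(i) (lo_hi[2, i] + lo_hi[1, i + 1L]) / 2, numeric(1))
}

new_bin_partition <- function(n_bins, cluster_type, breaks, seed) {
  structure(list(n_bins = n_bins, cluster_type = cluster_type,
                 breaks = as.numeric(breaks), seed = as.integer(seed)),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat("<bin_partition> ", x$n_bins, " bin(s), ", x$cluster_type, "\n", sep = "")
  if (length(x$breaks)) cat("  breaks: ", paste(signif(x$breaks, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' List the supported cluster types
#' @return Character vector of the eight cluster-type names.
#' @export
cluster_types <- function() {
  c("agglomerative_average", "agglomerative_complete", "agglomerative_single",
    "agglomerative_ward", "equal_distant", "equal_size", "gaussian_mixture", "k_means")
}

#' Assign values to the bins of a fitted partition
#'
#' Intervals are half-open `[lo, hi)` and exhaustive over the reals, so every
#' value (including values outside the training range) receives a bin; a
#' value equal to an interior boundary falls into the upper bin.
#'
#' @param partition A [fit_partition()] result.
#' @param values Numeric vector.
#' @return Integer vector of 1-based bin indices.
#' @export
assign_bin <- function(partition, values) {
  stopifnot(inherits(partition, "bin_partition"))
  if (partition$n_bins == 1L) return(rep(1L, length(values)))
  findInterval(as.numeric(values), partition$breaks) + 1L
}

# save/restore the global RNG state so seeded clustering does not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
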