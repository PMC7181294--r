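#' Fuse 3-axis channels by Euclidean magnitude
#'
#' For each sensor's (x, y, z) triplet the per-sample magnitude
#' sqrt(x^2 + y^2 + z^2) is computed. With several sensors the per-sensor
#' magnitude series are concatenated in the recording's deterministic
#' channel order, keeping the result univariate.
#'
#' @param channels named list of equal-length numeric vectors whose names
#'   end in \code{_x}, \code{_y}, \code{_z}; channel count must be a
#'   multiple of 3.
#' @return Numeric vector of fused values (all >= 0).
#' @export
fuse_magnitude <- function(channels) {
  nms <- names(channels)
  if (length(channels) %% 3L != 0L)
    stop("fusion error: channel count must be a multiple of 3")
  sensors <- unique(sub("_[xyz]$", "", nms))
  out <- lapply(sort(sensors), function(sn) {
    ax <- paste0(sn, "_", c("x", "y", "z"))
    if (!all(ax %in% nms))
      stop("fusion error: sensor '", sn, "' lacks a full x/y/z triplet")
    sqrt(channels[[ax[1]]]^2 + channels[[ax[2]]]^2 + channels[[ax[3]]]^2)
  })
  unlist(out, use.names = FALSE)
}

#' Fit a first-principal-component fusion on training recordings
#'
#' Learns the unit-norm loading vector of the first principal component of
#' the pooled sample-by-channel matrix of the training recordings. The sign
#' is fixed so the loading's largest-magnitude coefficient is positive. The
#' fitted loading is reused unchanged at apply time, so no test information
#' leaks into training.
#'
#' @param train_recordings list of \code{har_recording} objects sharing the
#'   same channel set.
#' @return An object of class \code{"har_pca"} with elements \code{loading}
#'   (named), \code{center} and \code{var_share} (PC1 share of variance).
#' @export
fit_pca_fusion <- function(train_recordings) {
  if (length(train_recordings) < 2L && n_samples(train_recordings[[1L]]) < 2L)
    stop("need at least 2 training samples to fit PCA")
  mats <- lapply(train_recordings, function(r)
    do.call(cbind, r$channels))
  X <- do.call(rbind, mats)
  if (nrow(X) < 2L) stop("need at least 2 training samples to fit PCA")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  S <- crossprod(Xc) / (nrow(Xc) - 1L)
  if (all(abs(S) < 1e-12))
    stop("degenerate-basis error: zero-variance training matrix")
  eig <- eigen(S, symmetric = TRUE)
  v <- eig$vectors[, 1L]
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  names(v) <- colnames(X)
  structure(list(loading = v, center = ctr,
                 var_share = eig$values[1L] / sum(pmax(eig$values, 0))),
            class = "har_pca")
}

#' Project a recording's channels onto a fitted first principal component
#'
#' @param fit a \code{"har_pca"} object from \code{\link{fit_pca_fusion}}.
#' @param channels named list of channels matching the fitted loading.
#' @return Numeric vector of PC1 scores, same length as the channels.
#' @export
apply_pca_fusion <- function(fit, channels) {
  X <- do.call(cbind, channels[names(fit$loading)])
  drop(sweep(X, 2L, fit$center) %*% fit$loading)
}

#' Fuse channels by concatenation
#'
#' Appends the channels end-to-end in their stored (deterministic) order;
#' no value is altered and no dimensionality reduction is applied, so the
#' result has length n x (channel count).
#'
#' @param channels named list of equal-length numeric vectors.
#' @return Numeric vector of the concatenated values.
#' @export
fuse_concatenate <- function(channels) {
  if (length(channels) == 0L) stop("fusion error: no channels")
  unlist(channels, use.names = FALSE)
}

#' Fuse a recording into a univariate series
#'
#' @param recording a \code{har_recording}.
#' @param method one of \code{"concatenation"} (default), \code{"magnitude"},
#'   \code{"pca"}.
#' @param pca_fit required when \code{method = "pca"}: a fitted
#'   \code{"har_pca"} from \code{\link{fit_pca_fusion}} on training data.
#' @return Numeric vector.
#' @export
fuse_recording <- function(recording,
                           method = c("concatenation", "magnitude", "pca"),
                           pca_fit = NULL) {
  method <- match.arg(method)
  switch(method,
         concatenation = fuse_concatenate(recording$channels),
         magnitude = fuse_magnitude(recording$channels),
         pca = {
           if (is.null(pca_fit))
             stop("method 'pca' requires a fitted 'pca_fit'")
           apply_pca_fusion(pca_fit, recording$channels)
         })
}
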