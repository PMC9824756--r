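# Pluggable deep-feature backends.
#
# The pipeline only requires: image in, fixed-length feature vector out,
# deterministically. The reference configuration is a pretrained
# ImageNet-architecture GoogLeNet's final fully connected (1000-way) layer,
# pre-softmax; since no deep-learning runtime ships with this package, that
# backend raises an explicit error unless a runtime + weights are provided,
# and the "mock" backend — a fixed seeded projection — stands in for all
# testing. Downstream stages are backend-agnostic.

backend_registry <- new.env(parent = emptyenv())

#' Register a deep-feature backend
#'
#' A backend is a list with fields `name`, `input_size`, `n_features`, and
#' `fun(rgb_array) -> numeric(n_features)`. Output length is checked at
#' registration against a probe image.
#'
#' @param backend Backend list as described above.
#' @return The backend, invisibly.
#' @export
register_backend <- function(backend) {
  stopifnot(is.list(backend), is.character(backend$name),
            is.function(backend$fun), backend$n_features >= 1)
  probe <- array(0, dim = c(backend$input_size, backend$input_size, 3))
  out <- backend$fun(probe)
  if (length(out) != backend$n_features) {
    stop(sprintf("backend '%s' declared %d features but produced %d",
                 backend$name, backend$n_features, length(out)))
  }
  assign(backend$name, backend, envir = backend_registry)
  invisible(backend)
}

#' Fetch a registered backend by name
#'
#' `"mock"` (the deterministic projection backend) and `"googlenet"` (the
#' reference pretrained-CNN configuration; errors without a deep-learning
#' runtime) are pre-registered.
#'
#' @param name Backend name, optionally with options, e.g.
#'   `list(name = "mock", seed = 99)`.
#' @return A backend list.
#' @export
get_backend <- function(name = "mock") {
  opts <- list()
  if (is.list(name)) { opts <- name[-1]; name <- name$name %||% name[[1]] }
  if (identical(name, "mock")) return(do.call(mock_backend, opts))
  if (!exists(name, envir = backend_registry)) {
    stop(sprintf("unknown deep backend '%s'; registered: %s", name,
                 paste(ls(backend_registry), collapse = ", ")))
  }
  get(name, envir = backend_registry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cache for the mock projection matrices, keyed by seed.
mock_proj_cache <- new.env(parent = emptyenv())

#' Deterministic mock deep backend
#'
#' Pools the input image with 7x7 block means to a 32x32 grid (every pixel
#' has nonzero pooling weight), averages the three channels, flattens to
#' 1024 values and multiplies by a fixed seeded 1000 x 1024 matrix whose
#' entries are `sign * U(0.1, 1)` — no zero entries, so two images differing
#' in any single pixel yield different feature vectors. Linear: the all-zero
#' image maps to the all-zero vector.
#'
#' @param seed Seed of the fixed projection matrix.
#' @param input_size Expected image side; must be a multiple of the 32-cell
#'   pooling grid (default 224 = 7 * 32).
#' @return A backend list usable with [extract_deep()].
#' @export
mock_backend <- function(seed = 20230498, input_size = 224) {
  grid <- 32L
  if (input_size %% grid != 0) {
    stop(sprintf("mock backend input_size must be a multiple of %d", grid))
  }
  key <- sprintf("s%d", seed)
  W <- if (exists(key, envir = mock_proj_cache)) get(key, envir = mock_proj_cache)
  else {
    W <- with_seed(seed, {
      m <- matrix(stats::runif(1000 * grid^2, 0.1, 1), nrow = 1000)
      m * sample(c(-1, 1), length(m), replace = TRUE)
    })
    assign(key, W, envir = mock_proj_cache)
    W
  }
  block <- input_size %/% grid
  list(
    name = sprintf("mock(seed=%d)", seed),
    input_size = as.integer(input_size),
    n_features = 1000L,
    fun = function(rgb) {
      g <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
      # 7x7 block means via row/col aggregation
      pooled <- t(rowsum(t(rowsum(g, rep(seq_len(grid), each = block))),
                         rep(seq_len(grid), each = block))) / block^2
      as.numeric(W %*% as.numeric(pooled))
    }
  )
}

#' Extract the deep half of the raw feature vector
#'
#' @param image A `spectro_image` from [render_image()] or a 3-channel
#'   array matching the backend's declared input size.
#' @param backend A backend list from [get_backend()] / [mock_backend()].
#' @return Numeric feature vector with attributes `backend_name` and
#'   `input_hash` (digest of the image fed in). Same backend + same image
#'   always yields identical values.
#' @export
#' @examples
#' img <- array(0, dim = c(224, 224, 3))
#' f <- extract_deep(img, mock_backend())
#' length(f)  # 1000
extract_deep <- function(image, backend = get_backend("mock")) {
  rgb <- if (inherits(image, "spectro_image")) image$rgb else image
  if (!(is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] == 3)) {
    stop("image must be a 3-channel array or a spectro_image")
  }
  if (dim(rgb)[1] != backend$input_size || dim(rgb)[2] != backend$input_size) {
    stop(sprintf("backend '%s' expects a %d x %d image, got %d x %d",
                 backend$name, backend$input_size, backend$input_size,
                 dim(rgb)[1], dim(rgb)[2]))
  }
  v <- backend$fun(rgb)
  structure(as.numeric(v), backend_name = backend$name,
            input_hash = digest::digest(rgb))
}

# Placeholder for the reference pretrained-CNN backend: explicit guidance
# rather than a silent fallback.
googlenet_backend_stub <- function() {
  list(name = "googlenet", input_size = 224L, n_features = 1000L,
       fun = function(rgb) {
         stop(paste("the 'googlenet' backend needs a deep-learning runtime and",
                    "pretrained weights, which are not installed; use the",
                    "'mock' backend, or register_backend() a wrapper around",
                    "your own runtime"))
       })
}

.onLoad <- function(libname, pkgname) {
  # register directly: the stub's fun errors by design, so skip the probe
  assign("googlenet", googlenet_backend_stub(), envir = backend_registry)
}
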