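#' @keywords internal
"_PACKAGE"

# Run an expression under a local Mersenne-Twister RNG state, restoring the
# caller's state afterwards so package randomness never leaks into user code.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stop_rbpnn <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop_rbpnn("'%s' must be a single integer >= %d (got %s)", name, min,
               paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_feature_map <- function(x, name = "feature map") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop_rbpnn("%s must be a C x H x W array", name)
  }
  invisible(x)
}

#' Flatten a feature map into a channel-by-position matrix
#'
#' Converts a `C x H x W` feature map into a `C x (H*W)` matrix using the
#' package-wide row-major spatial convention: position `p = (i-1)*W + j`
#' for pixel row `i` and column `j`. Every reshape in the package (attention
#' maps, comprehensive feature matrices, convolution patches) uses this one
#' convention.
#'
#' @param x A `C x H x W` numeric array.
#' @return A `C x (H*W)` numeric matrix.
#' @seealso [matrix_to_map()]
#' @export
map_to_matrix <- function(x) {
  check_feature_map(x)
  d <- dim(x)
  matrix(aperm(x, c(1L, 3L, 2L)), nrow = d[1L])
}

#' Reshape a channel-by-position matrix back into a feature map
#'
#' Inverse of [map_to_matrix()] for a known spatial size.
#'
#' @param m A `C x (H*W)` numeric matrix.
#' @param h,w Spatial height and width.
#' @return A `C x H x W` numeric array.
#' @export
matrix_to_map <- function(m, h, w) {
  if (!is.matrix(m) || ncol(m) != h * w) {
    stop_rbpnn("matrix has %d columns; expected H*W = %d", ncol(m), h * w)
  }
  aperm(array(m, dim = c(nrow(m), w, h)), c(1L, 3L, 2L))
}

# Row-wise numerically stabilized softmax of a matrix.
row_softmax <- function(e) {
  e <- e - apply(e, 1L, max)
  ex <- exp(e)
  ex / rowSums(ex)
}
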