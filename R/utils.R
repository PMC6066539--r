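# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
with_preserved_seed <- function(seed, code) {
  # Mersenne-Twister + inversion, fixed explicitly so simulations are
  # reproducible across platforms and R option changes.
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Round half away from zero
#'
#' Integer rounding in the convention used for printed percentages: 0.5 always
#' rounds away from zero (so 94.5 -> 95, -94.5 -> -95), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 78.98, -0.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Two-sample t test that tolerates zero-variance groups (exact-mean synthetic
# data): equal constant groups give p = 1, different constant groups p = 0.
# Returns list(t, df, p, mean_diff) with mean_diff = mean(y) - mean(x).
safe_t_test <- function(x, y, var_equal = FALSE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("safe_t_test() needs at least two finite observations per group")
  }
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  diff <- my - mx
  if (vx == 0 && vy == 0) {
    if (diff == 0) {
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1, mean_diff = 0))
    }
    return(list(t = sign(diff) * Inf, df = length(x) + length(y) - 2L,
                p = 0, mean_diff = diff))
  }
  nx <- length(x); ny <- length(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- diff / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df), mean_diff = diff)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#' Identical partitions (up to label permutation) score 1; independent random
#' partitions score about 0. Unassigned labels (e.g. module 0) are treated as
#' an ordinary class.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number, the adjusted Rand index.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Timestamped leveled logging to stderr; level controlled by
# options(stressmem.log_level = "info" | "debug" | "warn" | "off").
log_msg <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, off = 4L)
  threshold <- levels[[getOption("stressmem.log_level", "warn")]]
  if (levels[[level]] < threshold) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(..., collapse = "")))
  invisible(NULL)
}
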