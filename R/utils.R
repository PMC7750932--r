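# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing validation failures carry a class so callers and tests can
#' distinguish input-shape problems from numerical failures.
#' @noRd
kliclust_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "kliclust_error")))
}

input_error     <- function(msg) kliclust_error(msg, "kliclust_input_error")
config_error    <- function(msg) kliclust_error(msg, "kliclust_config_error")
alignment_error <- function(msg) kliclust_error(msg, "kliclust_alignment_error")
parse_error     <- function(msg) kliclust_error(msg, "kliclust_parse_error")
numeric_error   <- function(msg) kliclust_error(msg, "kliclust_numeric_error")

#' Derive a reproducible sub-stream seed
#'
#' Folds a base seed and any number of integer indices into a single seed in
#' \[0, 2^31), using a Lehmer-style multiplicative hash carried out in double
#' precision (exact below 2^53). Used to give every stochastic sub-step
#' (resampling run, dataset, restart, candidate K) its own deterministic
#' stream.
#' @noRd
derive_seed <- function(seed, ...) {
  x <- (as.numeric(seed) %% 2147483629) + 1
  for (k in list(...)) {
    if (is.character(k)) k <- utf8ToInt(paste(k, collapse = ""))
    for (v in as.numeric(k)) {
      x <- (x * 48271 + v * 16807 + 1) %% 2147483647
    }
  }
  as.integer(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package internals do
#' not disturb the user's random stream. A NULL seed leaves the RNG alone.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Validate a square symmetric numeric matrix
#' @noRd
check_square_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    input_error(sprintf("%s must be a numeric matrix", what))
  }
  if (nrow(m) != ncol(m)) {
    input_error(sprintf("%s must be square, got %d x %d", what, nrow(m), ncol(m)))
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    input_error(sprintf("%s is not symmetric (max |m - t(m)| = %.3g)", what, asym))
  }
  invisible(TRUE)
}

#' k-means with restarts and degenerate-input fallback
#'
#' Thin wrapper around stats::kmeans. Hartigan-Wong with random restarts is
#' used first; when it fails (typically because sampled initial centres are
#' duplicated rows, which happens routinely on binary cluster-indicator data),
#' distinct unique rows are used as centres under Lloyd's algorithm. When the
#' data contain fewer distinct rows than K, each distinct row becomes its own
#' cluster (labels then use fewer than K of the labels 1..K).
#' @noRd
kmeans_restart <- function(x, K, n_restarts = 10, max_iter = 300, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (K > n) input_error(sprintf("K = %d exceeds number of observations (%d)", K, n))
  if (K == 1) return(rep(1L, n))
  # individual resampling runs may hit the Hartigan-Wong iteration caps on
  # heavily duplicated rows; the best-found solution is still returned and
  # those diagnostics are noise at H runs per consensus matrix
  muffle_kmeans <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("Quick-TRANSfer|did not converge|empty cluster",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  with_seed(seed, {
    fit <- tryCatch(
      muffle_kmeans(
        stats::kmeans(x, centers = K, nstart = n_restarts, iter.max = max_iter)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      ux <- unique(x)
      if (nrow(ux) >= K) {
        centers <- ux[sample.int(nrow(ux), K), , drop = FALSE]
        fit <- suppressWarnings(
          stats::kmeans(x, centers = centers, iter.max = max_iter, algorithm = "Lloyd")
        )
      } else {
        key <- apply(x, 1L, paste, collapse = "\r")
        return(as.integer(match(key, unique(key))))
      }
    }
    as.integer(fit$cluster)
  })
}
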