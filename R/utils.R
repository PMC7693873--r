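## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm binomial coef pnorm pchisq kruskal.test hclust
#'   cophenetic cor as.dist rbinom rnorm runif var sd setNames
#' @importFrom utils read.delim write.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_probability <- function(x, field, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop_field(field, if (open) "must be a single number in (0, 1)"
                      else "must be a single number in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) stop_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

# All permutations of 1..k as a list of integer vectors (k small; k <= 7 in use).
permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# The nine echocardiographic outcome variables the evaluation operates on.
phenotype_variables <- function() {
  c("elateral", "eseptal", "gcs", "gls", "grs",
    "sr_a", "sr_e", "sr_s", "sseptal")
}
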