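#' @importFrom stats cor rnorm runif rpois quantile predict coef glm binomial
#'   plogis var sd setNames dnorm
#' @importFrom utils read.table write.table head
NULL

# Abort with a classed condition so callers can distinguish error families.
grn_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "grnstack_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Rank-normalize a score vector to (0, 1]: average ranks for ties, divided by n.
rank_normalize <- function(x) {
  rank(x, ties.method = "average") / length(x)
}

# Sample excess kurtosis, population-moment form: m4/m2^2 - 3.
excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, abs(m))^2) {
    return(NA_real_)
  }
  mean((x - m)^4) / m2^2 - 3
}

edge_key <- function(regulator, target) paste(regulator, target, sep = "\r")
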