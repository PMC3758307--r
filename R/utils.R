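#' @importFrom rlang %||% .data
#' @importFrom stats lm anova coef cor pchisq pf pnorm pt ptukey qbeta
#'   quantile rbinom rnorm rpois runif sd setNames var optimize model.matrix
#'   median complete.cases
#' @importFrom utils head tail
NULL

# Stable, platform-independent child seed from a parent seed and a stage name.
# Keeps all derived seeds in [0, 2^31 - 1].
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480989
  as.integer((as.numeric(seed) %% 2147480989 * 69069 + h) %% 2147480989)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}

`%na%` <- function(x, default) ifelse(is.na(x), default, x)
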