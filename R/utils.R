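#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup desc n
#' @importFrom stats cor rnorm runif rpois rgamma rlnorm setNames
NULL

# five-flavor taxonomy of the Chinese materia medica
FLAVORS <- c("sour", "bitter", "sweet", "pungent", "salty")

# controlled vocabulary of traditional pharmacological effects (pinyin)
EFFECTS <- c(
  "Zhi Tong",   # analgesic
  "Jie Du",     # clearing toxic materials
  "Qu Shi",     # dispelling dampness
  "Xiao Zhong", # detumescence
  "Huo Xue",    # promoting blood circulation
  "Qu Feng",    # dispelling wind
  "San Han"     # eliminating cold
)

# pharmacophore feature kinds (GALAHAD-style abbreviations)
FEATURE_KINDS <- c("NP", "HY", "NC", "AA", "DA", "AR")

#' Render a number the way the package's reports print it
#'
#' Four decimal places, round-half-even (so 0.92857 prints as "0.9286").
#'
#' @param x numeric vector.
#' @param digits decimal places (default 4).
#' @return character vector.
#' @export
format_report_number <- function(x, digits = 4) {
  formatC(round(x, digits), format = "f", digits = digits)
}

# stable, platform-independent sub-seed from a master seed and a label,
# so each generator draws from its own stream and adding a generator
# never perturbs existing outputs
derive_seed <- function(seed, label) {
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 31 + cp) %% 1000003L
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# evaluate `code` under a dedicated RNG stream, leaving the caller's
# RNG state untouched
with_stream <- function(seed, label, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  force(code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
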