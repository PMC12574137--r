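#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef glm lm pnorm ppois qnorm rbinom rexp rnorm rpois
#'   runif rmultinom rgamma binomial poisson vcov sd var fisher.test
#'   p.adjust as.formula setNames quantile rank complete.cases pchisq
#'   residuals
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("premdd_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("premdd_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a reproducible sub-seed for a named random substream
#'
#' Each stochastic component draws from its own substream so that adding or
#' reordering simulators never perturbs the draws of another. The substream
#' seed is a deterministic hash of the master seed and the stream name.
#'
#' @param seed Master integer seed.
#' @param name Character substream name (e.g. `"cohort"`, `"dnm"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps everything in integer range
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% m
  as.integer(h)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > tol)
    stop_config(name, " must be non-negative and sum to 1 (got sum = ",
                format(sum(p)), ")")
  invisible(p)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop_data("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-c(1, 2)][nzchar(f[-c(1, 2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
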