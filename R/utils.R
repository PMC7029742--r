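#' @useDynLib lakemicro, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate anova aov coef cor cor.test dist lm logLik
#'   p.adjust pchisq quantile rbeta rgamma rmultinom rnorm runif sd setNames
#'   var weighted.mean
#' @importFrom utils combn read.delim write.table
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic entry points funnel through this so that a single seed
# argument fully determines their output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Write a table as TSV with a provenance header
#'
#' All pipeline outputs are TSV files whose first line is a `#`-prefixed
#' provenance comment (producing function, package version, and the seed
#' used, if any) so a result file is traceable to the call that made it.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param what label for the producing step.
#' @param seed seed recorded in the header, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, what = "lakemicro", seed = NULL) {
  header <- sprintf("# %s | lakemicro %s%s", what,
                    as.character(utils::packageVersion("lakemicro")),
                    if (is.null(seed)) "" else sprintf(" | seed=%d", as.integer(seed)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

# Benjamini-Hochberg adjustment; thin named wrapper so the family over which
# the correction is applied is explicit at each call site.
bh_adjust <- function(p) p.adjust(p, method = "BH")
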