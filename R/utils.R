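#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rlnorm runif cor p.adjust phyper setNames
#' @importFrom utils read.delim write.table head
#' @importFrom graphics plot
NULL

# Default 3' adapter: 21-nt Illumina GEX adapter core plus poly-A fill so
# that tag (21 nt) + adapter (28 nt) makes a 49-nt read.
DEFAULT_ADAPTER <- "TCGTATGCCGTCTTCTGCTTGAAAAAAA"

TAG_LEN <- 21L
ANCHOR <- "CATG"
READ_LEN <- 49L

# Round half away from zero (the convention that reproduces printed
# two-decimal report percentages; base round() is half-to-even).
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

pct <- function(num, den, digits = 2) {
  round_half_up(100 * num / den, digits)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

stop_param <- function(...) {
  stop(structure(class = c("deepsage_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("deepsage_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Stable RNG scoping: run `expr` under a seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stop_param("seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  if (length(len) == 1L) len <- rep(len, n)
  vapply(split(chars, rep(seq_len(n), len)), paste0, "", collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
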