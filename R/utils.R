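#' @importFrom stats median quantile rnorm runif rpois p.adjust wilcox.test setNames
#' @importFrom utils head tail write.table read.table
#' @importFrom data.table data.table setkey setorder rbindlist .N
NULL

# let data.table NSE ([.data.table, .N) work inside this package
.datatable.aware <- TRUE

# classed error helper so callers can distinguish failure modes
xy_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "xyturnover_error")))
}

#' Evaluate an expression with a fixed RNG seed
#'
#' Saves and restores the global `.Random.seed`, so simulation functions are
#' pure functions of their `seed` argument and never perturb the caller's
#' random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    xy_error("invalid 'seed': must be a single integer", "xy_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# derive a per-stage child seed from a root seed (kept below 2^31)
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483629L
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path input path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write simulated reads to FASTQ
#'
#' Qualities are a constant placeholder (the read simulator does not model
#' base-quality decay).
#'
#' @param reads data frame with columns `id` and `seq`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param qual quality character used for every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  quals <- strrep(qual, nchar(reads$seq))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", quals), con)
  invisible(path)
}

#' Read a FASTQ file into a data frame
#' @param path input path (optionally gzipped).
#' @return data frame with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) xy_error("malformed FASTQ", "xy_io_error")
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  data.frame(id = ids, seq = lines[seq(2L, length(lines), by = 4L)],
             stringsAsFactors = FALSE)
}

# half-open interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
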