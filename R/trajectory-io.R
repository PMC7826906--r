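# Plain-text trajectory files: either one trajectory per line as a run
# of contiguous 0/1 characters, or a single-column file of 0/1 integers
# (one bit per line, read as a single trajectory). Whitespace is ignored;
# any other character is a parse error naming line and column.

#' Read binary trajectories from a text file
#'
#' @param path path to a text file with one trajectory per line of
#'   contiguous `0`/`1` characters, or a single-column file of `0`/`1`
#'   integers (interpreted as one trajectory).
#' @return a list of integer 0/1 vectors of class `"markov_trajectory"`
#'   (without `seed`/`params` attributes, which only simulated
#'   trajectories carry).
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no trajectories in ", path, call. = FALSE)
  parse_line <- function(line, lineno) {
    chars <- strsplit(gsub("[ \t,]", "", line), "")[[1]]
    bad <- which(!chars %in% c("0", "1"))
    if (length(bad)) {
      stop(sprintf("invalid character '%s' at line %d, column %d of %s",
                   chars[bad[1]], lineno, bad[1], path), call. = FALSE)
    }
    as.integer(chars)
  }
  bits_per_line <- mapply(parse_line, lines, seq_along(lines),
                          SIMPLIFY = FALSE, USE.NAMES = FALSE)
  # single-column layout: every line carries exactly one bit
  if (all(lengths(bits_per_line) == 1L) && length(bits_per_line) > 1L) {
    bits_per_line <- list(unlist(bits_per_line))
  }
  lapply(bits_per_line, function(b) {
    structure(b, class = "markov_trajectory")
  })
}

#' Write binary trajectories to a text file
#'
#' One trajectory per line, as contiguous `0`/`1` characters — the format
#' accepted by [read_trajectories()].
#'
#' @param trajs a single trajectory (0/1 vector) or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (!is.list(trajs)) trajs <- list(trajs)
  lines <- vapply(trajs, function(tr) {
    paste(as_bits(tr), collapse = "")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
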