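# shared internal helpers: condition constructors, rounding, residue alphabet

csom_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "coralsom_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

format_error <- function(fmt, ...) csom_stop("coralsom_format_error", fmt, ...)
vocab_error <- function(fmt, ...) csom_stop("coralsom_vocab_error", fmt, ...)
invariant_error <- function(fmt, ...) csom_stop("coralsom_invariant_error", fmt, ...)
contract_error <- function(fmt, ...) csom_stop("coralsom_contract_error", fmt, ...)
config_error <- function(fmt, ...) csom_stop("coralsom_config_error", fmt, ...)

# 20 standard residues plus X (unknown)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

AA20 <- AA_ALPHABET[AA_ALPHABET != "X"]
# K/R frequency boosted so random backbones cleave into usable tryptic
# peptides
AA_WEIGHTS <- ifelse(AA20 %in% c("K", "R"), 3, 1)

is_valid_sequence <- function(x) {
  nchar(x) >= 1L & !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
}

#' Round half away from zero
#'
#' Percentages in summaries are rounded half-up to a fixed number of decimal
#' places (so 8.35 -> 8.4), matching how headline overlap percentages are
#' conventionally printed; base `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

pct_of <- function(count, total, digits = 1) {
  if (total == 0) return(NA_real_)
  round_half_up(100 * count / total, digits)
}

# scalar checkers
check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    contract_error("%s must be TRUE or FALSE", what)
  x
}

check_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    contract_error("%s must be an integer >= %d", what, min)
  as.integer(x)
}

check_number <- function(x, what, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    contract_error("%s must be a number in [%s, %s]", what, min, max)
  as.numeric(x)
}

# stable file writing: LF endings, no quoting, fixed NA representation
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "", eol = "\n")
  invisible(path)
}

parse_bool_column <- function(x, column, rows) {
  out <- rep(NA, length(x))
  truthy <- c("TRUE", "true", "T", "1", "yes")
  falsy <- c("FALSE", "false", "F", "0", "no", "")
  out[x %in% truthy] <- TRUE
  out[x %in% falsy] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    format_error("column '%s': unparseable logical value '%s' (row %d)",
                 column, x[bad[1]], rows[bad[1]])
  out
}
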