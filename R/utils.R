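#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

ns_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

ns_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

ns_log <- function(fmt, ...) message(sprintf("[netscreen] %s", sprintf(fmt, ...)))

clip1 <- function(x) pmin(pmax(x, -1), 1)

#' Derive a reproducible per-stage seed from a global seed
#'
#' Pipeline stages draw their own seed from the run's global seed and the
#' stage name, so any stage can be re-run in isolation with the same stream.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(seed) %% 2147480000 + h * 7919) %% 2147483629 + 1)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483629))
  force(code)
}

# Minimal strict TSV reader: skips '#' comment lines and blank lines, checks
# the header and per-line field counts, and reports 1-based file line numbers
# in errors (read.delim cannot do that).
read_strict_tsv <- function(path, columns) {
  if (!file.exists(path)) ns_stop("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(columns)), columns),
                         stringsAsFactors = FALSE)
    attr(out, "lineno") <- integer(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  if (!identical(header, columns))
    ns_stop("%s: expected header '%s' but found '%s' (line %d)",
            path, paste(columns, collapse = "\t"), lines[1L], lineno[1L])
  body <- fields[-1L]
  lineno <- lineno[-1L]
  bad <- which(vapply(body, length, 1L) != length(columns))
  if (length(bad))
    ns_stop("%s: malformed row with %d field(s), expected %d (line %d): '%s'",
            path, length(body[[bad[1L]]]), length(columns), lineno[bad[1L]],
            lines[-1L][bad[1L]])
  mat <- if (length(body)) do.call(rbind, body) else
    matrix(character(0), 0, length(columns))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- columns
  for (j in seq_along(out)) out[[j]] <- trimws(out[[j]])
  attr(out, "lineno") <- lineno
  out
}

parse_sign_token <- function(tok, path = "<input>", lineno = NA_integer_) {
  out <- ifelse(tok %in% c("+", "+1"), 1,
                ifelse(tok %in% c("-", "-1"), -1, NA_real_))
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    ns_stop("%s: unknown sign token '%s' (line %s); accepted: + - +1 -1",
            path, tok[i], as.character(lineno[i]))
  }
  out
}

parse_num <- function(tok, what, path = "<input>", lineno = NA_integer_) {
  out <- suppressWarnings(as.numeric(tok))
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    ns_stop("%s: non-numeric %s '%s' (line %s)", path, what, tok[i],
            as.character(lineno[i]))
  }
  out
}

parse_flag <- function(tok, what, path = "<input>", lineno = NA_integer_) {
  up <- toupper(tok)
  out <- ifelse(up %in% c("TRUE", "T", "1"), TRUE,
                ifelse(up %in% c("FALSE", "F", "0"), FALSE, NA))
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    ns_stop("%s: missing or invalid %s flag '%s' (line %s)", path, what,
            tok[i], as.character(lineno[i]))
  }
  out
}

write_tsv_lines <- function(header, rows, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (length(rows)) writeLines(rows, con)
  invisible(path)
}

fmt_num <- function(x, digits = 10) {
  vapply(x, function(v) sprintf("%.*g", digits, v), character(1))
}
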