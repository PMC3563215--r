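#' Construct a ranked residue-residue contact list
#'
#' A `contact_list` holds predicted or structure-derived contacts for a single
#' protein chain of known length. Contacts are stored sorted by descending
#' score; pairs are normalized so that `i < j`.
#'
#' @param contacts data.frame with integer columns `i`, `j` and numeric
#'   `score`. Rows with `i > j` are swapped (with a warning); duplicate
#'   `(i, j)` pairs keep the higher score (with a warning).
#' @param length chain length L in residues; every `j` must be `<= length`.
#' @return An object of class `contact_list`: a list with elements `length`
#'   and `contacts` (data.frame `i`, `j`, `score`, sorted by descending
#'   score, ties broken by `i` then `j`).
#' @export
contact_list <- function(contacts, length) {
  stopifnot(is.data.frame(contacts), all(c("i", "j", "score") %in% names(contacts)))
  length <- as.integer(length)
  if (length < 1L) stop("chain length must be >= 1")
  i <- as.integer(contacts$i)
  j <- as.integer(contacts$j)
  score <- as.numeric(contacts$score)
  if (any(!is.finite(score))) stop("contact scores must be finite")
  if (any(i < 1L) || any(j < 1L)) stop("residue indices must be >= 1")
  swap <- i > j
  if (any(swap)) {
    warning(sum(swap), " contact(s) had i > j; indices swapped")
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  if (any(i == j)) stop("self-contacts (i == j) are not allowed")
  if (any(j > length)) stop("contact index exceeds chain length ", length)
  df <- data.frame(i = i, j = j, score = score)
  key <- paste(df$i, df$j)
  if (anyDuplicated(key)) {
    warning("duplicate contact pairs; keeping highest score per pair")
    df <- df[order(key, -df$score), ]
    df <- df[!duplicated(paste(df$i, df$j)), ]
  }
  df <- df[order(-df$score, df$i, df$j), ]
  rownames(df) <- NULL
  structure(list(length = length, contacts = df), class = "contact_list")
}

#' @export
print.contact_list <- function(x, ...) {
  cat("Contact list: chain length", x$length, "residues,",
      nrow(x$contacts), "contacts\n")
  if (nrow(x$contacts) > 0) {
    cat("  score range [", format(min(x$contacts$score), digits = 4), ", ",
        format(max(x$contacts$score), digits = 4), "]\n", sep = "")
    print(utils::head(x$contacts, 5))
    if (nrow(x$contacts) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.contact_list <- function(x) x$length

#' Read a CASP RR contact file
#'
#' Parses the community RR format for ranked contact predictions: optional
#' header lines (`PFRMAT`, `TARGET`, `AUTHOR`, `METHOD`, `MODEL`, `REMARK`,
#' `END`), optional sequence lines (amino-acid letters, used to infer the
#' chain length), then whitespace-separated records `i j dmin dmax prob`.
#'
#' @param path file path or connection.
#' @param length optional chain length override; otherwise inferred from the
#'   sequence lines, or from the largest residue index if no sequence given.
#' @return A [contact_list] sorted by descending probability.
#' @export
read_rr <- function(path, length = NULL) {
  len_override <- length
  length <- base::length # restore the function; the argument shadows it
  lines <- readLines(path, warn = FALSE)
  seq_len_chars <- 0L
  rec_i <- integer(0); rec_j <- integer(0); rec_p <- numeric(0)
  header_re <- "^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END|RMODE)"
  for (k in seq_along(lines)) {
    ln <- trimws(lines[[k]])
    if (ln == "" || grepl(header_re, ln)) next
    if (grepl("^[A-Za-z]+$", ln)) { # sequence line
      seq_len_chars <- seq_len_chars + nchar(ln)
      next
    }
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) < 5L || anyNA(suppressWarnings(as.numeric(fields[1:5]))))
      stop("malformed RR record at line ", k, ": '", lines[[k]], "'")
    rec_i <- c(rec_i, as.integer(fields[1]))
    rec_j <- c(rec_j, as.integer(fields[2]))
    rec_p <- c(rec_p, as.numeric(fields[5]))
  }
  L <- if (!is.null(len_override)) as.integer(len_override)
       else if (seq_len_chars > 0L) seq_len_chars
       else if (length(rec_j) > 0L) max(rec_i, rec_j)
       else stop("cannot determine chain length: no sequence lines and no records")
  contact_list(data.frame(i = rec_i, j = rec_j, score = rec_p), length = L)
}

#' Write a contact list in CASP RR format
#'
#' Scores are written in the probability column; `dmin`/`dmax` are fixed at
#' 0 and 8.
#'
#' @param cl a [contact_list].
#' @param path output file path.
#' @param target optional TARGET identifier for the header.
#' @export
write_rr <- function(cl, path, target = NULL) {
  stopifnot(inherits(cl, "contact_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("PFRMAT RR", con)
  if (!is.null(target)) writeLines(paste("TARGET", target), con)
  writeLines("MODEL 1", con)
  df <- cl$contacts
  if (nrow(df) > 0)
    writeLines(sprintf("%d %d 0 8 %.6g", df$i, df$j, df$score), con)
  writeLines("END", con)
  invisible(path)
}

#' Filter a contact list by sequence separation and rank
#'
#' Removes contacts with sequence separation `j - i < min_sep`, then keeps
#' the `top_n` highest-scoring of the remainder. This is the standard input
#' filter for the KDE boundary predictor (minimum separation 5, top 1000).
#'
#' @param cl a [contact_list].
#' @param min_sep minimum sequence separation retained (residues).
#' @param top_n maximum number of contacts retained.
#' @return A filtered [contact_list]; may be empty.
#' @export
filter_contacts <- function(cl, min_sep = 5, top_n = 1000) {
  stopifnot(inherits(cl, "contact_list"))
  if (top_n <= 0) stop("top_n must be positive")
  df <- cl$contacts
  df <- df[df$j - df$i >= min_sep, , drop = FALSE]
  if (nrow(df) > top_n) df <- df[seq_len(top_n), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(length = cl$length, contacts = df), class = "contact_list")
}
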