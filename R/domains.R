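#' Construct a domain annotation
#'
#' A `domain_annotation` partitions (possibly partially) the residues of a
#' chain into labeled domains. Each domain is a set of one or more segments
#' and may be discontinuous; residues covered by no segment are linkers and
#' carry no label. Domains receive ordinal labels 1, 2, ... by the position
#' of their first residue.
#'
#' @param segments list with one element per domain; each element a
#'   two-column matrix or data.frame of (start, end) residue ranges,
#'   1-based inclusive.
#' @param length chain length L.
#' @return An object of class `domain_annotation`: list with `length` and
#'   `domains` (list of two-column integer matrices, ordered by first
#'   residue).
#' @export
domain_annotation <- function(segments, length) {
  L <- as.integer(length)
  if (L < 1L) stop("chain length must be >= 1")
  doms <- lapply(segments, function(s) {
    m <- matrix(as.integer(as.matrix(s)), ncol = 2L)
    colnames(m) <- c("start", "end")
    if (any(m[, 1L] > m[, 2L])) stop("reversed segment range")
    if (any(m < 1L) || any(m > L)) stop("segment outside [1, ", L, "]")
    m[order(m[, 1L]), , drop = FALSE]
  })
  doms <- doms[order(vapply(doms, function(m) m[1L, 1L], integer(1)))]
  cover <- integer(L)
  for (m in doms)
    for (k in seq_len(nrow(m)))
      cover[m[k, 1L]:m[k, 2L]] <- cover[m[k, 1L]:m[k, 2L]] + 1L
  if (any(cover > 1L)) stop("overlapping domain segments at residue ",
                            which(cover > 1L)[1L])
  structure(list(length = L, domains = doms), class = "domain_annotation")
}

#' Parse a CATH-style chopping string
#'
#' Chopping strings encode domain architectures compactly: domains are
#' separated by `/`, discontinuous segments of one domain by `,`, and each
#' segment is `start-end` (1-based inclusive), e.g. `"1-50,151-200/51-150"`.
#'
#' @param text chopping string.
#' @param length chain length L.
#' @return A [domain_annotation].
#' @export
parse_chopping <- function(text, length) {
  text <- trimws(text)
  if (text == "") stop("empty chopping string")
  dom_strings <- strsplit(text, "/", fixed = TRUE)[[1]]
  segs <- lapply(dom_strings, function(d) {
    parts <- strsplit(trimws(d), ",", fixed = TRUE)[[1]]
    m <- t(vapply(parts, function(p) {
      se <- regmatches(p, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", p))[[1]]
      if (base::length(se) != 3L) stop("malformed segment '", p, "' in chopping string")
      as.integer(se[2:3])
    }, integer(2)))
    m
  })
  domain_annotation(segs, length = length)
}

#' Format a domain annotation as a chopping string
#'
#' @param ann a [domain_annotation].
#' @return character chopping string (`"1-100/101-200"` style).
#' @export
format_chopping <- function(ann) {
  stopifnot(inherits(ann, "domain_annotation"))
  paste(vapply(ann$domains, function(m)
    paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ","),
    character(1)), collapse = "/")
}

#' Per-residue domain labels
#'
#' @param ann a [domain_annotation].
#' @return integer vector of length L; residue r carries the ordinal label of
#'   its domain, or `NA` if it is a linker.
#' @export
label_residues <- function(ann) {
  stopifnot(inherits(ann, "domain_annotation"))
  lab <- rep(NA_integer_, ann$length)
  for (d in seq_along(ann$domains)) {
    m <- ann$domains[[d]]
    for (k in seq_len(nrow(m))) lab[m[k, 1L]:m[k, 2L]] <- d
  }
  lab
}

#' Number of domains in an annotation
#' @param ann a [domain_annotation].
#' @return integer count.
#' @export
n_domains <- function(ann) base::length(ann$domains)

#' @export
print.domain_annotation <- function(x, ...) {
  cat("Domain annotation: L =", x$length, "residues,",
      n_domains(x), "domain(s)\n")
  cat(" ", format_chopping(x), "\n")
  nlab <- sum(!is.na(label_residues(x)))
  if (nlab < x$length) cat("  ", x$length - nlab, "linker residue(s)\n")
  invisible(x)
}

# Convert sorted interior cut points into a contiguous domain partition:
# cuts c1 < c2 < ... start new domains, i.e. [1, c1-1], [c1, c2-1], ..., [ck, L].
# min_domain > 0 drops (left to right) cuts that would create a segment
# shorter than min_domain.
cuts_to_domains <- function(cuts, L, min_domain = 0) {
  cuts <- sort(unique(as.integer(cuts)))
  cuts <- cuts[cuts > 1L & cuts <= L]
  if (min_domain > 0 && base::length(cuts) > 0) {
    kept <- integer(0)
    prev <- 1L
    for (cp in cuts) {
      if (cp - prev >= min_domain) { kept <- c(kept, cp); prev <- cp }
    }
    while (base::length(kept) > 0 && L - kept[base::length(kept)] + 1L < min_domain)
      kept <- kept[-base::length(kept)]
    cuts <- kept
  }
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, L)
  domain_annotation(lapply(seq_along(starts),
                           function(k) cbind(starts[k], ends[k])), length = L)
}
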