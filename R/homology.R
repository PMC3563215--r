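#' Assemble an alignment-endpoint profile
#'
#' The homology baseline predicts boundaries where homologous-domain
#' alignments tend to start or end. This step counts, per residue, how many
#' alignments start there plus how many end there.
#'
#' @param endpoints data.frame with columns `ali_start` and `ali_end`
#'   (1-based inclusive alignment coordinates on the query chain).
#' @param L chain length.
#' @return An object of class `endpoint_profile`: numeric count vector of
#'   length L.
#' @export
assemble_endpoint_profile <- function(endpoints, L) {
  stopifnot(is.data.frame(endpoints),
            all(c("ali_start", "ali_end") %in% names(endpoints)))
  L <- as.integer(L)
  s <- as.integer(endpoints$ali_start)
  e <- as.integer(endpoints$ali_end)
  bad <- which(s < 1L | e > L | s > e)
  if (base::length(bad) > 0L)
    stop("endpoint record ", bad[1L], " out of range: start=", s[bad[1L]],
         " end=", e[bad[1L]], " for L=", L)
  counts <- tabulate(s, nbins = L) + tabulate(e, nbins = L)
  structure(as.numeric(counts), class = "endpoint_profile")
}

#' Smooth a profile by repeated moving averaging
#'
#' Applies `iterations` passes of a (2*window + 1)-point moving average,
#' truncated at the chain ends (end positions average over the available
#' points only, so total mass is conserved up to end effects). Repeated
#' application converges toward a flat profile; the variance across
#' positions is nonincreasing in the iteration count.
#'
#' @param profile numeric per-residue vector (e.g. an
#'   [assemble_endpoint_profile]).
#' @param window half-window in residues, >= 1.
#' @param iterations number of averaging passes.
#' @return smoothed numeric vector of the same length and class.
#' @export
smooth_by_averaging <- function(profile, window = 5, iterations = 10) {
  stopifnot(window >= 1, iterations >= 0)
  v <- as.numeric(profile)
  L <- base::length(v)
  idx <- seq_len(L)
  lo <- pmax(1L, idx - as.integer(window))
  hi <- pmin(L, idx + as.integer(window))
  for (it in seq_len(iterations)) {
    cs <- c(0, cumsum(v))
    v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  structure(v, class = class(profile))
}

#' Predict domains from a smoothed endpoint profile
#'
#' Candidate boundaries are the local peaks of the smoothed endpoint
#' profile. Peaks are taken in order of decreasing height (ties toward the
#' lower position) and accepted greedily, forbidding boundaries closer than
#' `min_dist` residues to either sequence terminus or to any previously
#' accepted boundary. Chains shorter than `2 * min_dist + 1` therefore
#' always come back as a single domain.
#'
#' @param profile smoothed [endpoint_profile] (numeric per-residue vector).
#' @param min_dist exclusion distance in residues (default 60).
#' @param w slope half-window for peak detection.
#' @return An object of classes `homology_prediction` and
#'   `domain_annotation`, with elements `profile` and `cuts`.
#' @export
predict_from_endpoints <- function(profile, min_dist = 60, w = 5) {
  v <- as.numeric(profile)
  L <- base::length(v)
  peaks <- if (any(v > 0)) find_peak_points(v, w = w) else integer(0)
  peaks <- peaks[order(-v[peaks], peaks)]
  accepted <- integer(0)
  for (p in peaks) {
    if (p - 1L < min_dist || L - p < min_dist) next
    if (base::length(accepted) > 0L && any(abs(accepted - p) < min_dist)) next
    accepted <- c(accepted, p)
  }
  ann <- cuts_to_domains(accepted, L)
  ann$profile <- v
  ann$cuts <- sort(accepted)
  class(ann) <- c("homology_prediction", "domain_annotation")
  ann
}

#' @export
print.homology_prediction <- function(x, ...) {
  cat("Homology endpoint-profile prediction: L =", x$length, "residues,",
      n_domains(x), "domain(s)\n")
  cat("  chopping:", format_chopping(x), "\n")
  invisible(x)
}

#' Read an alignment-endpoint table
#'
#' Tab-separated columns `target_id`, `ali_start`, `ali_end`, `bitscore`
#' (1-based inclusive coordinates), one row per domain alignment, as
#' produced by an upstream HMM search.
#'
#' @param path TSV file path.
#' @return data.frame with those four columns.
#' @export
read_endpoints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("target_id", "ali_start", "ali_end", "bitscore")
  if (!all(need %in% names(df)))
    stop("endpoint table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_endpoints
#' @param endpoints data.frame as returned by [read_endpoints].
#' @export
write_endpoints <- function(endpoints, path) {
  utils::write.table(endpoints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
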