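# Independent reference implementations used to cross-check the package.
# These deliberately use the naive direct formulation (loops, all-pairs),
# not the package's vectorized code paths.

# Triple-loop contact-cut density: for each contact, for each residue r
# strictly between the pair, add a Gaussian centered at r; normalize.
profile_oracle <- function(cl, sigma) {
  L <- cl$length
  dens <- numeric(L)
  pos <- seq_len(L)
  df <- cl$contacts
  for (k in seq_len(nrow(df))) {
    i <- df$i[k]; j <- df$j[k]
    if (j - i > 1L)
      for (r in (i + 1L):(j - 1L))
        dens <- dens + stats::dnorm((pos - r) / sigma) / sigma
  }
  dens / sum(dens)
}

# All-pairs pseudo-C-beta contact set by double loop.
contacts_oracle <- function(coords, threshold = 8.0) {
  pcb <- pseudo_cbeta(coords)
  n <- nrow(pcb)
  out <- NULL
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      d <- sqrt(sum((pcb[i, ] - pcb[j, ])^2))
      if (d <= threshold) out <- rbind(out, c(i, j, -d))
    }
  if (is.null(out)) data.frame(i = integer(0), j = integer(0), score = numeric(0))
  else data.frame(i = out[, 1], j = out[, 2], score = out[, 3])
}

# Brute-force interval-overlap rescaling of a 1000-cell profile to length L.
rescale_oracle <- function(b, L) {
  out <- numeric(L)
  for (r in seq_len(L)) {
    lo <- 1000 * (r - 1) / L
    hi <- 1000 * r / L
    for (cell in 0:999) {
      ov <- min(hi, cell + 1) - max(lo, cell)
      if (ov > 0) out[r] <- out[r] + b[cell + 1] * ov
    }
  }
  out
}

# Blocking-pair check for a stable-marriage result on an overlap matrix.
# Preferences are totalized as in the implementation: higher overlap first,
# ties toward the lower index; an unmatched side prefers any partner.
# Returns TRUE if the matching is stable (no blocking pair).
is_stable_matching <- function(m, matching) {
  nr <- nrow(m); nc <- ncol(m)
  ref_match <- rep(NA_integer_, nr)
  pred_match <- rep(NA_integer_, nc)
  for (k in seq_along(matching)) {
    r <- as.integer(names(matching)[k]); p <- as.integer(matching[k])
    ref_match[r] <- p; pred_match[p] <- r
  }
  prefers <- function(v_new, i_new, v_cur, i_cur) {
    if (is.na(i_cur)) return(TRUE)
    v_new > v_cur || (v_new == v_cur && i_new < i_cur)
  }
  for (r in seq_len(nr))
    for (p in seq_len(nc)) {
      if (!is.na(ref_match[r]) && ref_match[r] == p) next
      r_wants <- prefers(m[r, p], p,
                         if (is.na(ref_match[r])) NA else m[r, ref_match[r]],
                         ref_match[r])
      p_wants <- prefers(m[r, p], r,
                         if (is.na(pred_match[p])) NA else m[pred_match[p], p],
                         pred_match[p])
      if (r_wants && p_wants) return(FALSE)
    }
  TRUE
}

# Fraction of true boundaries matched by a predicted cut within +-tol.
boundary_recovery <- function(targets, tol = 10, ...) {
  hit <- 0L; tot <- 0L
  for (tg in targets) {
    pred <- predict_domains_kde(tg$contacts, ...)
    tot <- tot + length(tg$boundaries)
    for (b in tg$boundaries)
      if (length(pred$cuts) > 0 && min(abs(pred$cuts - b)) <= tol)
        hit <- hit + 1L
  }
  hit / tot
}

# Dense two-block contact list: all pairs within [1, split] and within
# [split+1, L] at separations sep_range; nothing crosses the split.
two_block_contacts <- function(L = 100, split = 50, sep_range = c(5, 30)) {
  rows <- list()
  blocks <- list(c(1L, split), c(split + 1L, L))
  for (b in blocks)
    for (i in b[1]:(b[2] - sep_range[1]))
      for (j in (i + sep_range[1]):min(i + sep_range[2], b[2]))
        rows[[length(rows) + 1L]] <- c(i, j)
  m <- do.call(rbind, rows)
  contact_list(data.frame(i = m[, 1], j = m[, 2], score = 1), length = L)
}

# Turn a per-residue label vector (NA = linker) into a domain_annotation:
# all runs sharing a label belong to one (possibly discontinuous) domain.
labels_to_annotation <- function(labels) {
  L <- length(labels)
  segs <- list()
  for (lab in sort(unique(labels[!is.na(labels)]))) {
    in_dom <- !is.na(labels) & labels == lab
    r <- rle(in_dom)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs[[length(segs) + 1L]] <- cbind(starts[r$values], ends[r$values])
  }
  domain_annotation(segs, length = L)
}

# Random contiguous domain partition for property tests.
random_partition <- function(L, max_domains = 4) {
  k <- sample.int(max_domains, 1L)
  cuts <- if (k > 1L) sort(sample(2:L, k - 1L)) else integer(0)
  starts <- c(1L, cuts); ends <- c(cuts - 1L, L)
  keep <- starts <= ends
  domain_annotation(lapply(which(keep), function(q)
    cbind(starts[q], ends[q])), length = L)
}
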