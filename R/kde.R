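#' Bandwidth selection for the contact-cut profile
#'
#' Computes the Gaussian kernel standard deviation (the bandwidth, in
#' residues) from the chain length `L` under one of five schemes:
#'
#' * `fixed`: a constant `c`;
#' * `linear`: `L / n` (the default scheme, with `n = 15`);
#' * `log`: `log_k(L)`;
#' * `power`: `L^(1/x)`;
#' * `amise`: the plug-in bandwidth minimizing the asymptotic mean
#'   integrated squared error of the kernel density estimate, solved by the
#'   secant method on the AMISE fixed-point equation (see Details).
#'
#' @details For the `amise` scheme the sample is the multiset of kernel
#' centers the profile is built from (every residue strictly between a
#' contact pair, with multiplicity), so a `contacts` argument is required.
#' With a Gaussian kernel the AMISE-optimal bandwidth satisfies
#' `h = (R(K) / (n * R(f'')))^(1/5)` with `R(K) = 1/(2*sqrt(pi))`; the
#' curvature functional `R(f'')` is itself estimated by a Gaussian KDE with
#' bandwidth `h`, and the resulting fixed-point equation is solved by the
#' secant method started from 1 and `L` (tolerance 1e-6, at most 100
#' iterations, falling back to the normal-reference bandwidth if the
#' iteration leaves (0, L]).
#'
#' @param L chain length (residues), >= 1.
#' @param scheme either a string `"kind:parameter"` (e.g. `"linear:15"`,
#'   `"fixed:5"`, `"log:2"`, `"power:2"`, `"amise"`) or a list with elements
#'   `kind` and `parameter`.
#' @param contacts a [contact_list]; required for `scheme = "amise"`.
#' @return positive numeric bandwidth (sigma, residues).
#' @export
compute_bandwidth <- function(L, scheme = "linear:15", contacts = NULL) {
  s <- parse_bandwidth_scheme(scheme)
  sigma <- switch(s$kind,
    fixed  = s$parameter,
    linear = L / s$parameter,
    log    = log(L) / log(s$parameter),
    power  = L^(1 / s$parameter),
    amise  = amise_bandwidth(L, contacts),
    stop("unknown bandwidth scheme kind '", s$kind, "'"))
  if (!is.finite(sigma) || sigma <= 0)
    stop("bandwidth scheme ", s$kind, " gave non-positive sigma for L = ", L)
  sigma
}

parse_bandwidth_scheme <- function(scheme) {
  if (is.list(scheme)) {
    kind <- scheme$kind
    parameter <- if (is.null(scheme$parameter)) NA_real_ else as.numeric(scheme$parameter)
  } else {
    parts <- strsplit(as.character(scheme), ":", fixed = TRUE)[[1]]
    kind <- parts[1]
    parameter <- if (base::length(parts) > 1L) as.numeric(parts[2]) else NA_real_
  }
  kind <- match.arg(kind, c("fixed", "linear", "log", "power", "amise"))
  if (kind != "amise") {
    if (!is.finite(parameter) || parameter <= 0)
      stop("bandwidth scheme '", kind, "' needs a positive parameter")
    if (kind == "log" && parameter <= 1)
      stop("log bandwidth scheme needs base > 1")
  }
  list(kind = kind, parameter = parameter)
}

# Kernel-center counts: c[r] = number of filtered contacts (i, j) with
# i < r < j. Shared by the profile builder and the AMISE estimator.
kernel_center_counts <- function(cl) {
  L <- cl$length
  df <- cl$contacts
  d <- numeric(L + 1L)
  span <- df$j - df$i
  keep <- span > 1L # separation-1 contacts have no strictly-between residue
  for (k in which(keep)) {
    d[df$i[k] + 1L] <- d[df$i[k] + 1L] + 1
    d[df$j[k]] <- d[df$j[k]] - 1
  }
  cumsum(d)[seq_len(L)]
}

amise_bandwidth <- function(L, contacts) {
  if (is.null(contacts))
    stop("amise bandwidth needs the contact list the profile is built from")
  cc <- kernel_center_counts(contacts)
  n <- sum(cc)
  if (n < 2) stop("amise bandwidth needs at least 2 kernel centers")
  pos <- seq_along(cc)
  # R(f_h'') for a Gaussian KDE on weighted integer positions:
  # (1/(n^2 h^5)) * sum_{r,s} c_r c_s phi4((r-s)/h), phi4 = 4th Hermite * phi
  rf2 <- function(h) {
    u <- outer(pos, pos, "-") / h
    phi4 <- (u^4 - 6 * u^2 + 3) * stats::dnorm(u)
    sum((cc %o% cc) * phi4) / (n^2 * h^5)
  }
  rk <- 1 / (2 * sqrt(pi))
  g <- function(h) h - (rk / (n * max(rf2(h), 1e-12)))^(1 / 5)
  h0 <- 1; h1 <- L
  f0 <- g(h0); f1 <- g(h1)
  for (iter in seq_len(100)) {
    if (abs(f1 - f0) < 1e-15) break
    h2 <- h1 - f1 * (h1 - h0) / (f1 - f0)
    if (!is.finite(h2) || h2 <= 0 || h2 > 10 * L) {
      # secant left the admissible range; fall back to normal reference
      h2 <- normal_reference_bw(cc)
      return(h2)
    }
    h0 <- h1; f0 <- f1
    h1 <- h2; f1 <- g(h1)
    if (abs(h1 - h0) < 1e-6) break
  }
  if (!is.finite(h1) || h1 <= 0) h1 <- normal_reference_bw(cc)
  h1
}

normal_reference_bw <- function(cc) {
  pos <- seq_along(cc)
  n <- sum(cc)
  mu <- sum(pos * cc) / n
  sd <- sqrt(sum(cc * (pos - mu)^2) / max(n - 1, 1))
  max(1.06 * sd * n^(-1 / 5), 0.5)
}

#' Smoothed contact-cut profile
#'
#' Builds the per-residue density whose minima mark candidate domain
#' boundaries. For every contact (i, j) a Gaussian of standard deviation
#' `sigma` is centered on each residue strictly between i and j; the summed
#' density is evaluated at integer positions 1..L and normalized to unit
#' sum. High values mark contact-dense (intra-domain) regions, low values
#' mark positions where a chain cut would disrupt few contacts.
#'
#' @param cl a [contact_list] (typically already passed through
#'   [filter_contacts]).
#' @param sigma Gaussian kernel standard deviation (residues), > 0.
#' @return An object of class `boundary_profile`: numeric vector of length
#'   L summing to 1, with attributes `sigma` and `n_centers`.
#' @export
contact_cut_profile <- function(cl, sigma) {
  stopifnot(inherits(cl, "contact_list"), sigma > 0)
  if (nrow(cl$contacts) == 0L)
    stop("no contacts; cannot build a boundary profile")
  L <- cl$length
  cc <- kernel_center_counts(cl)
  if (sum(cc) == 0)
    stop("no contacts with separation > 1; cannot build a boundary profile")
  pos <- seq_len(L)
  centers <- which(cc > 0)
  dens <- stats::dnorm(outer(pos, centers, "-"), sd = sigma) %*% cc[centers]
  dens <- as.vector(dens)
  dens <- dens / sum(dens)
  structure(dens, class = "boundary_profile", sigma = sigma,
            n_centers = sum(cc))
}

#' @export
print.boundary_profile <- function(x, ...) {
  cat("Boundary profile: L =", base::length(x), "residues, sigma =",
      format(attr(x, "sigma"), digits = 4), "\n")
  cat("  density range [", format(min(x), digits = 3), ", ",
      format(max(x), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.boundary_profile <- function(x, cuts = NULL, ...) {
  graphics::plot(seq_along(x), as.numeric(x), type = "l",
                 xlab = "residue", ylab = "cut density", ...)
  if (!is.null(cuts)) graphics::abline(v = cuts, col = "red", lty = 2)
  invisible(x)
}

#' Local slope of a profile
#'
#' Estimates the first derivative of a per-residue profile at position `p`
#' as the ordinary least-squares slope of the values over the window of `w`
#' residues either side (11 points for the default `w = 5`), truncated at
#' the chain ends. A centered finite-difference alternative is available for
#' sensitivity checks.
#'
#' @param profile numeric per-residue vector (e.g. a [contact_cut_profile]).
#' @param p position, `1 <= p <= L` (vectorized).
#' @param w half-window in residues.
#' @param method `"ols"` (default) or `"central"` (symmetric difference over
#'   the same window).
#' @return numeric slope(s).
#' @export
estimate_slope <- function(profile, p, w = 5, method = c("ols", "central")) {
  method <- match.arg(method)
  v <- as.numeric(profile)
  L <- base::length(v)
  vapply(as.integer(p), function(pp) {
    lo <- max(1L, pp - w); hi <- min(L, pp + w)
    x <- lo:hi
    y <- v[x]
    if (method == "ols") {
      xm <- x - mean(x)
      denom <- sum(xm^2)
      if (denom == 0) return(0)
      sum(xm * (y - mean(y))) / denom
    } else {
      (v[hi] - v[lo]) / (hi - lo)
    }
  }, numeric(1))
}

slope_profile <- function(profile, w = 5, method = "ols") {
  estimate_slope(profile, seq_along(as.numeric(profile)), w = w, method = method)
}

# Sign-change scan shared by minimum and maximum detection. For minima a
# candidate is where the slope turns from negative to nonnegative; plateaus
# (zero-slope runs) report the central index, ties to the lower index. A
# zero run followed by a further descent (minima) / ascent (maxima) is a
# shelf, not an extremum.
sign_change_points <- function(s, direction = c("min", "max")) {
  direction <- match.arg(direction)
  if (direction == "max") s <- -s
  L <- base::length(s)
  pts <- integer(0)
  p <- 2L
  while (p <= L) {
    if (s[p - 1L] < 0 && s[p] >= 0) {
      if (s[p] == 0) {
        q <- p
        while (q < L && s[q + 1L] == 0) q <- q + 1L
        nxt <- if (q < L) s[q + 1L] else 0
        if (nxt >= 0) pts <- c(pts, p + (q - p) %/% 2L)
        p <- q + 1L
        next
      }
      pts <- c(pts, p)
    }
    p <- p + 1L
  }
  pts[pts > 1L & pts < L]
}

#' Locate cut points in a boundary profile
#'
#' Finds the local minima of the smoothed profile via the windowed slope
#' estimate: a cut point is a position where the slope changes sign from
#' negative to nonnegative scanning left to right. Plateau minima report
#' their central position (ties to the lower index); positions 1 and L are
#' never reported. A monotone or flat profile yields no cut points (a
#' single-domain prediction).
#'
#' @param profile a [contact_cut_profile] or numeric per-residue vector.
#' @param w slope half-window (residues).
#' @param method slope estimator passed to [estimate_slope].
#' @return sorted integer vector of cut positions, strictly inside (1, L).
#' @export
find_cut_points <- function(profile, w = 5, method = "ols") {
  s <- slope_profile(profile, w = w, method = method)
  sign_change_points(s, "min")
}

find_peak_points <- function(profile, w = 5, method = "ols") {
  s <- slope_profile(profile, w = w, method = method)
  sign_change_points(s, "max")
}

#' Predict domain boundaries by kernel density smoothing
#'
#' The full contact-based pipeline: filter the contact list (minimum
#' sequence separation, top-N by score), choose the bandwidth, build the
#' smoothed contact-cut profile, and cut the chain at its local minima.
#' Domains are contiguous and labeled ordinally; the method never predicts
#' discontinuous domains. An empty filtered contact list yields a
#' single-domain prediction with a warning.
#'
#' @param cl a [contact_list].
#' @param bandwidth bandwidth scheme (see [compute_bandwidth]); default
#'   `"linear:15"`, i.e. sigma = L/15.
#' @param top_n,min_sep contact filter parameters (see [filter_contacts]).
#' @param w slope half-window for minimum detection.
#' @param min_domain minimum domain length enforced on the cuts (0 = none).
#' @param slope_method slope estimator (`"ols"` or `"central"`).
#' @return An object of classes `kde_prediction` and `domain_annotation`,
#'   with extra elements `profile` (the [contact_cut_profile], or NULL if no
#'   usable contacts), `cuts`, `sigma` and `n_contacts_used`.
#' @export
predict_domains_kde <- function(cl, bandwidth = "linear:15", top_n = 1000,
                                min_sep = 5, w = 5, min_domain = 0,
                                slope_method = "ols") {
  stopifnot(inherits(cl, "contact_list"))
  fl <- filter_contacts(cl, min_sep = min_sep, top_n = top_n)
  L <- fl$length
  if (nrow(fl$contacts) == 0L) {
    warning("no contacts left after filtering; returning single-domain prediction")
    ann <- cuts_to_domains(integer(0), L)
    ann$profile <- NULL; ann$cuts <- integer(0)
    ann$sigma <- NA_real_; ann$n_contacts_used <- 0L
    class(ann) <- c("kde_prediction", "domain_annotation")
    return(ann)
  }
  sigma <- compute_bandwidth(L, bandwidth, contacts = fl)
  prof <- contact_cut_profile(fl, sigma)
  cuts <- find_cut_points(prof, w = w, method = slope_method)
  ann <- cuts_to_domains(cuts, L, min_domain = min_domain)
  ann$profile <- prof
  ann$cuts <- cuts
  ann$sigma <- sigma
  ann$n_contacts_used <- nrow(fl$contacts)
  class(ann) <- c("kde_prediction", "domain_annotation")
  ann
}

#' @export
print.kde_prediction <- function(x, ...) {
  cat("KDE domain prediction: L =", x$length, "residues,",
      n_domains(x), "domain(s)\n")
  cat("  sigma =", format(x$sigma, digits = 4),
      "| contacts used =", x$n_contacts_used, "\n")
  cat("  chopping:", format_chopping(x), "\n")
  invisible(x)
}

#' @export
plot.kde_prediction <- function(x, ...) {
  if (is.null(x$profile)) stop("prediction has no profile (no usable contacts)")
  plot(x$profile, cuts = x$cuts, ...)
}
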