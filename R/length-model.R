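#' Fit the Bayesian chain-length domain-count model
#'
#' The naive length-based predictor rests on a simple Bayesian model: the
#' prior P(N) over the domain count classes N in \{1, 2, 3, 4+\} is the
#' class frequency in the training set; the likelihood f_N(L) of a chain
#' length L given N is a Gaussian kernel density estimate over the training
#' lengths of that class (Silverman's rule-of-thumb bandwidth per class);
#' and for each class a length-independent boundary-position profile b_N is
#' accumulated on a 1000-cell grid, every chain being scaled to length 1000
#' (boundary at residue p of a chain of length L falls in cell
#' `floor(1000*(p-1)/L)`), then smoothed with a Gaussian kernel (Silverman
#' bandwidth over the cell positions) and normalized to unit sum. The
#' single-domain class has no boundaries; its profile is identically zero.
#'
#' @param training data.frame with columns `length` (chain length),
#'   `n_domains` (integer >= 1; counts >= 4 are pooled into the "4+" class)
#'   and `boundaries`: either a list-column of integer vectors or a
#'   character column of `;`-separated positions (empty for single-domain
#'   chains). Boundary positions are cut points: the first residue of each
#'   domain after the first.
#' @return An object of class `length_model`: list with `priors` (named,
#'   sums to 1), `lengths` (per-class list of training lengths plus
#'   Silverman bandwidth) and `profiles` (4 x 1000 matrix of boundary
#'   densities, rows "1", "2", "3", "4+").
#' @export
fit_length_model <- function(training) {
  stopifnot(is.data.frame(training),
            all(c("length", "n_domains", "boundaries") %in% names(training)))
  bl <- training$boundaries
  if (is.character(bl)) {
    bl <- lapply(bl, function(s) {
      s <- trimws(s)
      if (s == "" || s == "-") integer(0)
      else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  classes <- c("1", "2", "3", "4+")
  cls <- ifelse(training$n_domains >= 4L, "4+", as.character(training$n_domains))
  missing_cls <- setdiff(classes, unique(cls))
  if (base::length(missing_cls) > 0L)
    stop("no training records for class(es): ", paste(missing_cls, collapse = ", "))
  priors <- as.numeric(table(factor(cls, levels = classes))) / nrow(training)
  names(priors) <- classes
  lengths <- lapply(classes, function(k) {
    ls <- as.numeric(training$length[cls == k])
    list(samples = ls,
         bw = if (base::length(ls) > 1L && stats::sd(ls) > 0)
                stats::bw.nrd0(ls) else max(1, 0.1 * mean(ls)))
  })
  names(lengths) <- classes
  cells <- 0:999
  profiles <- matrix(0, 4L, 1000L, dimnames = list(classes, NULL))
  for (k in classes) {
    rows <- which(cls == k)
    bcells <- unlist(lapply(rows, function(r) {
      b <- bl[[r]]
      if (base::length(b) == 0L) return(numeric(0))
      L <- training$length[r]
      if (any(b <= 1L | b > L)) stop("boundary outside (1, L] in record ", r)
      floor(1000 * (b - 1) / L)
    }))
    if (base::length(bcells) == 0L) next # class "1": zero profile
    bw <- if (base::length(bcells) > 1L && stats::sd(bcells) > 0)
      stats::bw.nrd0(bcells) else 10
    dens <- rowSums(stats::dnorm(outer(cells, bcells, "-"), sd = bw))
    profiles[k, ] <- dens / sum(dens)
  }
  structure(list(priors = priors, lengths = lengths, profiles = profiles,
                 n_training = nrow(training)),
            class = "length_model")
}

#' @export
print.length_model <- function(x, ...) {
  cat("Chain-length domain-count model (", x$n_training, " training chains)\n",
      sep = "")
  cat("  priors:", paste(sprintf("P(%s)=%.3f", names(x$priors), x$priors),
                         collapse = ", "), "\n")
  med <- vapply(x$lengths, function(e) stats::median(e$samples), numeric(1))
  cat("  median class lengths:",
      paste(sprintf("%s: %.0f", names(med), med), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior over the number of domains given chain length
#'
#' `P(N|L)` is proportional to `f_N(L) * P(N)`, normalized over the four
#' classes. If every class density is zero at L (far outside the training
#' support) the priors are returned with a warning.
#'
#' @param model a fitted [fit_length_model].
#' @param L chain length, >= 1.
#' @return named numeric vector over classes `1`, `2`, `3`, `4+`, summing
#'   to 1.
#' @export
posterior_ndomains <- function(model, L) {
  stopifnot(inherits(model, "length_model"), L >= 1)
  lik <- vapply(model$lengths, function(e)
    mean(stats::dnorm(L, mean = e$samples, sd = e$bw)), numeric(1))
  post <- lik * model$priors
  if (sum(post) <= 0) {
    warning("all class densities zero at L = ", L, "; falling back to priors")
    return(model$priors)
  }
  post / sum(post)
}

#' Rescale a 1000-cell boundary profile to a chain length
#'
#' Each residue r of a chain of length L receives the profile mass of the
#' cell interval `[1000*(r-1)/L, 1000*r/L)`; cells straddling a residue
#' border contribute proportionally, so total mass is conserved (for a
#' chain of length 100, residue 1 receives cells 0-9 exactly).
#'
#' @param b numeric vector of 1000 cell values.
#' @param L target chain length, >= 1.
#' @return numeric per-residue vector of length L with the same total mass.
#' @export
rescale_profile <- function(b, L) {
  stopifnot(base::length(b) == 1000L, L >= 1)
  cum <- stats::approxfun(0:1000, c(0, cumsum(b)), rule = 2)
  edges <- 1000 * (0:L) / L
  diff(cum(edges))
}

#' Predict domains from chain length alone
#'
#' The naive predictor: mixes the class boundary profiles by the posterior
#' `P(N|L)` (or, with `map_n = TRUE`, uses only the maximum a posteriori
#' class), rescales to length L, and cuts the chain wherever the profile
#' has a local peak under the windowed slope estimator used by the KDE
#' predictor. No peak yields a single-domain prediction.
#'
#' @param object a fitted [fit_length_model].
#' @param L chain length to predict for.
#' @param map_n use only the MAP class profile instead of the full mixture.
#' @param w slope half-window for peak detection.
#' @param ... unused.
#' @return An object of classes `naive_prediction` and `domain_annotation`,
#'   with elements `profile` (per-residue boundary density) and `posterior`.
#' @export
predict.length_model <- function(object, L, map_n = FALSE, w = 5, ...) {
  post <- posterior_ndomains(object, L)
  if (map_n) {
    k <- which.max(post)
    weights <- stats::setNames(as.numeric(seq_along(post) == k), names(post))
  } else weights <- post
  prof <- numeric(L)
  for (k in names(weights))
    if (weights[k] > 0)
      prof <- prof + weights[k] * rescale_profile(object$profiles[k, ], L)
  cuts <- if (any(prof > 0)) find_peak_points(prof, w = w) else integer(0)
  ann <- cuts_to_domains(cuts, L)
  ann$profile <- prof
  ann$posterior <- post
  class(ann) <- c("naive_prediction", "domain_annotation")
  ann
}

#' @export
print.naive_prediction <- function(x, ...) {
  cat("Naive length-based prediction: L =", x$length, "residues,",
      n_domains(x), "domain(s)\n")
  cat("  posterior:", paste(sprintf("P(%s|L)=%.3f", names(x$posterior),
                                    x$posterior), collapse = ", "), "\n")
  cat("  chopping:", format_chopping(x), "\n")
  invisible(x)
}

#' Serialize / restore a length model as JSON
#'
#' The JSON carries a format version, the priors, the per-class KDE sample
#' points and bandwidths, and the 1000-cell profiles, so a fitted model can
#' be shipped and reloaded exactly.
#'
#' @param model a [fit_length_model] object.
#' @param path file path.
#' @return `read_length_model` returns a `length_model`.
#' @export
write_length_model <- function(model, path) {
  stopifnot(inherits(model, "length_model"))
  obj <- list(format = "domaincut-length-model", version = 1L,
              priors = as.list(model$priors),
              lengths = lapply(model$lengths, function(e)
                list(samples = e$samples, bw = e$bw)),
              profiles = lapply(seq_len(nrow(model$profiles)),
                                function(r) model$profiles[r, ]),
              classes = rownames(model$profiles),
              n_training = model$n_training)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_length_model
#' @export
read_length_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "domaincut-length-model")
    stop("not a length-model JSON file: ", path)
  classes <- obj$classes
  profiles <- if (is.matrix(obj$profiles)) obj$profiles
              else do.call(rbind, obj$profiles)
  rownames(profiles) <- classes
  lengths <- lapply(obj$lengths, function(e)
    list(samples = as.numeric(e$samples), bw = as.numeric(e$bw)))
  names(lengths) <- classes
  structure(list(priors = stats::setNames(unlist(obj$priors), classes),
                 lengths = lengths, profiles = profiles,
                 n_training = obj$n_training),
            class = "length_model")
}
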