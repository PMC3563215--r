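#' Specification for a synthetic multidomain contact map
#'
#' Describes the statistical structure the contact-based boundary predictor
#' assumes: residue pairs within a domain are in contact more often than
#' pairs across domains, intra-domain contact probability decays with
#' sequence separation, and a fraction of the reported list is random
#' noise. True contacts draw scores from a high-score distribution, noise
#' from a low-score one, with deliberate overlap.
#'
#' @param domains integer vector of domain lengths (residues, each >= 20).
#' @param p_intra per-pair intra-domain contact probability (before decay).
#' @param p_inter per-pair inter-domain contact probability;
#'   `p_inter < p_intra`.
#' @param lambda sequence-separation decay scale (residues) for the
#'   intra-domain probability `p_intra * exp(-(j - i) / lambda)`.
#' @param noise_frac fraction of the emitted contact list drawn uniformly at
#'   random from non-contact pairs, in `[0, 1)`.
#' @param score_true,score_noise `c(shape1, shape2)` of the Beta score
#'   distributions for true and noise contacts.
#' @param min_sep minimum sequence separation of generated pairs.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(domains, p_intra = 0.08, p_inter = 0.005, lambda = 30,
                     noise_frac = 0.2, score_true = c(5, 2),
                     score_noise = c(2, 5), min_sep = 5) {
  domains <- as.integer(domains)
  if (any(domains < 20L)) stop("every domain must be >= 20 residues")
  if (!(p_inter >= 0 && p_inter < p_intra && p_intra <= 1))
    stop("need 0 <= p_inter < p_intra <= 1")
  if (noise_frac < 0 || noise_frac >= 1) stop("noise_frac must be in [0, 1)")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(domains = domains, p_intra = p_intra, p_inter = p_inter,
                 lambda = lambda, noise_frac = noise_frac,
                 score_true = score_true, score_noise = score_noise,
                 min_sep = as.integer(min_sep)),
            class = "sim_spec")
}

#' Generate a synthetic multidomain contact list
#'
#' Draws contacts pair by pair under a [sim_spec]: a same-domain pair (i, j)
#' is a true contact with probability `p_intra * exp(-(j-i)/lambda)`, a
#' cross-domain pair with probability `p_inter`; only pairs with separation
#' `>= min_sep` are candidates. Noise pairs are then sampled uniformly from
#' the remaining candidates so that they make up `noise_frac` of the final
#' list. Scores come from the spec's Beta distributions. Deterministic for a
#' fixed seed.
#'
#' @param spec a [sim_spec].
#' @param seed integer RNG seed (`set.seed`); `NULL` uses the current RNG
#'   state.
#' @return list with `contacts` (a [contact_list]), `boundaries` (true cut
#'   points: the first residue of each domain after the first) and
#'   `annotation` (the true [domain_annotation]).
#' @export
generate_multidomain_contacts <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  L <- sum(spec$domains)
  K <- base::length(spec$domains)
  dom_of <- rep(seq_len(K), spec$domains)
  ut <- which(upper.tri(matrix(FALSE, L, L)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  keep <- (j - i) >= spec$min_sep
  i <- i[keep]; j <- j[keep]
  same <- dom_of[i] == dom_of[j]
  p <- ifelse(same, spec$p_intra * exp(-(j - i) / spec$lambda), spec$p_inter)
  is_true <- stats::runif(base::length(p)) < p
  n_true <- sum(is_true)
  if (n_true == 0L) stop("spec produced no true contacts; increase p_intra")
  n_noise <- round(n_true * spec$noise_frac / (1 - spec$noise_frac))
  pool <- which(!is_true)
  if (n_noise > base::length(pool))
    stop("infeasible spec: not enough non-contact pairs for the requested noise_frac")
  noise_idx <- if (n_noise > 0L) sample(pool, n_noise) else integer(0)
  ti <- c(i[is_true], i[noise_idx])
  tj <- c(j[is_true], j[noise_idx])
  sc <- c(stats::rbeta(n_true, spec$score_true[1], spec$score_true[2]),
          stats::rbeta(n_noise, spec$score_noise[1], spec$score_noise[2]))
  cl <- contact_list(data.frame(i = ti, j = tj, score = sc), length = L)
  starts <- cumsum(c(1L, spec$domains[-K]))
  ends <- cumsum(spec$domains)
  ann <- domain_annotation(lapply(seq_len(K),
                                  function(k) cbind(starts[k], ends[k])),
                           length = L)
  list(contacts = cl, boundaries = starts[-1L], annotation = ann)
}

#' Ideal alpha-helix C-alpha trace
#'
#' Deterministic helical coordinates (radius 2.3 A, rise 1.5 A per residue,
#' 100 degrees of rotation per residue), giving the canonical ~3.8 A
#' consecutive C-alpha spacing. Used as a geometry fixture for pseudo-C-beta
#' and contact-threshold checks.
#'
#' @param n number of residues, >= 3.
#' @return numeric `n x 3` coordinate matrix.
#' @export
generate_helix_coordinates <- function(n) {
  if (n < 3L) stop("need at least 3 residues")
  t <- (seq_len(n) - 1L) * 100 * pi / 180
  cbind(x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * (seq_len(n) - 1L))
}

#' Generate a synthetic chain-length training set
#'
#' Draws `n` chains for fitting the naive length-based predictor: a domain
#' count class from `priors` (the "4+" class occasionally yields 5 domains),
#' a chain length from a per-class lognormal, and boundary positions at
#' uniform spacing plus Gaussian jitter, kept strictly inside the chain.
#'
#' @param n number of chains.
#' @param priors class probabilities for 1, 2, 3 and 4+ domains (sums to 1).
#' @param meanlog,sdlog per-class lognormal parameters for chain length.
#' @param jitter_frac boundary jitter standard deviation as a fraction of
#'   the inter-boundary spacing.
#' @param seed integer RNG seed; `NULL` uses the current state.
#' @return data.frame with columns `length`, `n_domains` and `boundaries`
#'   (`;`-separated positions, empty string for single-domain chains), ready
#'   for [fit_length_model].
#' @export
generate_length_training_set <- function(n, priors = c(0.5, 0.3, 0.15, 0.05),
                                         meanlog = log(c(150, 300, 450, 600)),
                                         sdlog = rep(0.25, 4),
                                         jitter_frac = 0.15, seed = NULL) {
  if (abs(sum(priors) - 1) > 1e-9) stop("priors must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  cls <- sample.int(4L, n, replace = TRUE, prob = priors)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    N <- if (cls[k] < 4L) cls[k] else 4L + stats::rbinom(1L, 1L, 0.25)
    L <- max(round(stats::rlnorm(1, meanlog[cls[k]], sdlog[cls[k]])), 30L * N)
    b <- integer(0)
    if (N > 1L) {
      spacing <- L / N
      for (attempt in 1:20) {
        b <- 1L + round(spacing * seq_len(N - 1L) +
                          stats::rnorm(N - 1L, 0, jitter_frac * spacing))
        b <- as.integer(b)
        if (all(b > 2L) && all(b < L) && all(diff(b) > 0)) break
        b <- integer(0)
      }
      if (base::length(b) == 0L) b <- 1L + round(spacing * seq_len(N - 1L))
    }
    out[[k]] <- data.frame(length = L, n_domains = N,
                           boundaries = paste(b, collapse = ";"))
  }
  do.call(rbind, out)
}

#' Read / write a training-set TSV
#'
#' Columns `length`, `n_domains`, `boundaries` (`;`-separated, empty for
#' single-domain chains).
#'
#' @param path TSV file path.
#' @export
read_training_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer", "character"),
                          na.strings = NULL)
  df$boundaries[is.na(df$boundaries)] <- ""
  df
}

#' @rdname read_training_set
#' @param training data.frame as produced by [generate_length_training_set].
#' @export
write_training_set <- function(training, path) {
  utils::write.table(training, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a seeded benchmark set of synthetic targets
#'
#' Draws `n` independent targets for benchmarking the boundary predictors:
#' each target has a domain count sampled uniformly from `n_domains`, domain
#' lengths sampled uniformly from `domain_length`, and a contact list drawn
#' under the default [sim_spec] (overridable via `spec_args`). All draws
#' come from one seeded stream, so the whole set is reproducible
#' bit-for-bit.
#'
#' @param n number of targets.
#' @param seed integer RNG seed; `NULL` uses the current state.
#' @param n_domains integer vector of admissible domain counts.
#' @param domain_length `c(min, max)` domain length range (residues).
#' @param spec_args named list of overrides passed to [sim_spec].
#' @return list of `n` elements, each as returned by
#'   [generate_multidomain_contacts].
#' @export
generate_benchmark_set <- function(n, seed = NULL, n_domains = 2:4,
                                   domain_length = c(50, 120),
                                   spec_args = list()) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(k) {
    K <- if (base::length(n_domains) == 1L) n_domains
         else sample(n_domains, 1L)
    lens <- sample(seq(domain_length[1], domain_length[2]), K, replace = TRUE)
    spec <- do.call(sim_spec, c(list(domains = lens), spec_args))
    generate_multidomain_contacts(spec, seed = NULL)
  })
}

#' Generate synthetic alignment-endpoint samples
#'
#' Emulates the output of a homologous-domain search: alignment start/end
#' pairs that cluster (Gaussian jitter, clipped to the chain) around the
#' true domain termini implied by `boundaries`.
#'
#' @param boundaries true cut points (first residue of each domain after the
#'   first); empty for a single domain.
#' @param L chain length.
#' @param n number of alignments.
#' @param jitter_sd Gaussian jitter standard deviation (residues); 0 places
#'   every endpoint exactly on a domain terminus.
#' @param seed integer RNG seed; `NULL` uses the current state.
#' @return data.frame with columns `target_id`, `ali_start`, `ali_end`,
#'   `bitscore`.
#' @export
generate_endpoint_samples <- function(boundaries, L, n = 200, jitter_sd = 5,
                                      seed = NULL) {
  boundaries <- sort(as.integer(boundaries))
  if (any(boundaries <= 1L | boundaries > L))
    stop("boundaries must lie strictly inside (1, L]")
  if (!is.null(seed)) set.seed(seed)
  starts <- c(1L, boundaries)
  ends <- c(boundaries - 1L, L)
  d <- sample.int(base::length(starts), n, replace = TRUE)
  s <- pmin(pmax(round(stats::rnorm(n, starts[d], jitter_sd)), 1L), L)
  e <- pmin(pmax(round(stats::rnorm(n, ends[d], jitter_sd)), 1L), L)
  swap <- s > e
  tmp <- s[swap]; s[swap] <- e[swap]; e[swap] <- tmp
  data.frame(target_id = "synthetic", ali_start = as.integer(s),
             ali_end = as.integer(e),
             bitscore = round(stats::runif(n, 50, 300), 1))
}
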