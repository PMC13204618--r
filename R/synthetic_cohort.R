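#' Patch archetype specifications
#'
#' A synthetic whole-slide cohort is built from six patch phenotypes
#' ("archetypes"): low-grade tumor, high-grade tumor, necrosis, fibrosis,
#' normal parenchyma, and imaging artifact. Each archetype is an isotropic
#' Gaussian blob in embedding space, emulating the clustered structure that
#' foundation-model patch embeddings exhibit for distinct tissue phenotypes.
#'
#' Archetype centers are rows of the discrete sine basis scaled to norm
#' `separation`, so they are mutually orthogonal (for `d >= 6`) and
#' deterministic in `d`.
#'
#' `hazard_weight` is the grade loading of the archetype: within a slide's
#' tumor patches the mixing probability of archetypes with weight 1 equals
#' the slide's latent grade g. Exactly the `tumor_*` archetypes carry
#' `is_tumor = TRUE`.
#'
#' @param d embedding dimension (>= 2).
#' @param separation Euclidean norm of each archetype center; larger values
#'   make phenotype clusters more separable. Default 4 against unit spread.
#' @param spread per-dimension Gaussian noise scale around the center
#'   (tissue archetypes).
#' @param artifact_spread noise scale of the artifact archetype. Artifacts
#'   (air bubbles, folds, pen ink, blur) are morphologically diverse, so
#'   their embeddings scatter far more widely than any coherent tissue
#'   phenotype; the default 6 disperses them across the embedding space.
#' @return data.frame with one row per archetype (`name`, `is_tumor`,
#'   `hazard_weight`, `spread`) and the center matrix in
#'   `attr(, "means")` (6 x d).
#' @export
default_archetypes <- function(d, separation = 4, spread = 1,
                               artifact_spread = 6) {
  check_number(d, "d", min = 2); check_number(separation, "separation", positive = TRUE)
  check_number(spread, "spread", positive = TRUE)
  check_number(artifact_spread, "artifact_spread", positive = TRUE)
  names6 <- c("tumor_low", "tumor_high", "necrosis", "fibrosis", "normal", "artifact")
  k <- seq_len(d)
  means <- t(vapply(seq_along(names6), function(j) {
    v <- sin(pi * j * k / (d + 1))
    separation * v / sqrt(sum(v^2))
  }, numeric(d)))
  rownames(means) <- names6
  out <- data.frame(
    name = names6,
    is_tumor = names6 %in% c("tumor_low", "tumor_high"),
    hazard_weight = c(0, 1, 0, 0, 0, 0),
    spread = c(spread, spread, spread, spread, spread, artifact_spread),
    stringsAsFactors = FALSE
  )
  attr(out, "means") <- means
  out
}

#' Synthetic cohort configuration
#'
#' Holds every knob of the synthetic whole-slide cohort generator. Defaults
#' describe the reference world used throughout the package: 200 slides of
#' 48-80 patches in a 32-dimensional embedding space, about 35% tumor
#' patches, a strong grade signal (log hazard ratio 2 per SD of latent
#' grade), exponential event times at 0.02 events/month at the average
#' grade, and an equal censoring intensity (roughly half the cohort
#' censored).
#'
#' @param n_slides number of slides (>= 2).
#' @param patches_min,patches_max range of patches per slide (uniform).
#' @param embed_dim embedding dimension d (>= 2).
#' @param beta grade signal: log hazard ratio per standard deviation of the
#'   latent grade (0 = no prognostic signal).
#' @param baseline_rate exponential event rate (events/month) at eta = 0.
#' @param censor_rate exponential censoring intensity (per month); 0 means
#'   no censoring.
#' @param tumor_fraction expected share of tumor patches per slide.
#' @param nontumor_mix mixing proportions of the non-tumor remainder over
#'   `c(normal, fibrosis, necrosis, artifact)`; must sum to 1.
#' @param separation,spread,artifact_spread archetype geometry, see
#'   [default_archetypes()].
#' @param seed integer RNG seed; the cohort is a pure function of the config.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_slides = 200, patches_min = 48, patches_max = 80,
                          embed_dim = 32, beta = 2, baseline_rate = 0.02,
                          censor_rate = 0.02, tumor_fraction = 0.35,
                          nontumor_mix = c(normal = 0.70, fibrosis = 0.10,
                                           necrosis = 0.05, artifact = 0.15),
                          separation = 4, spread = 1, artifact_spread = 6,
                          seed = 1L) {
  check_number(n_slides, "n_slides", min = 2)
  check_number(patches_min, "patches_min", min = 1)
  check_number(patches_max, "patches_max", min = patches_min)
  check_number(embed_dim, "embed_dim", min = 2)
  check_number(beta, "beta")
  check_number(baseline_rate, "baseline_rate", positive = TRUE)
  check_number(censor_rate, "censor_rate", min = 0)
  check_number(tumor_fraction, "tumor_fraction", min = 0)
  if (tumor_fraction > 1) stop_param("tumor_fraction must be in [0, 1]")
  if (length(nontumor_mix) != 4 || abs(sum(nontumor_mix) - 1) > 1e-8 ||
      any(nontumor_mix < 0) ||
      !setequal(names(nontumor_mix), c("normal", "fibrosis", "necrosis", "artifact")))
    stop_param("nontumor_mix must be non-negative proportions named normal/fibrosis/necrosis/artifact summing to 1")
  check_number(seed, "seed")
  structure(list(n_slides = as.integer(n_slides),
                 patches_min = as.integer(patches_min),
                 patches_max = as.integer(patches_max),
                 embed_dim = as.integer(embed_dim), beta = beta,
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 tumor_fraction = tumor_fraction,
                 nontumor_mix = nontumor_mix,
                 separation = separation, spread = spread,
                 artifact_spread = artifact_spread,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample survival records under a proportional-hazards generator
#'
#' Event times are exponential with rate `baseline_rate * exp(eta)`,
#' censoring times exponential with rate `censor_rate`; the observed time
#' is the minimum and the event indicator flags whether death came first
#' (ties count as events). `censor_rate = 0` gives fully observed deaths.
#'
#' @param eta numeric vector of per-slide log hazards.
#' @param config a [cohort_config()] (only the two rates are used).
#' @return data.frame with columns `time` (months) and `event` (0/1).
#' @export
sample_survival <- function(eta, config) {
  if (!inherits(config, "cohort_config")) stop_param("config must be a cohort_config")
  n <- length(eta)
  t_event <- stats::rexp(n, rate = config$baseline_rate * exp(eta))
  if (config$censor_rate > 0) {
    t_cens <- stats::rexp(n, rate = config$censor_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
             event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic whole-slide cohort
#'
#' Each slide draws a latent grade \eqn{g_i \sim Beta(2, 2)} on \[0, 1\].
#' Tumor patches (a Binomial(`N_i`, `tumor_fraction`) count) mix the
#' high-grade archetype with probability \eqn{g_i} and the low-grade
#' archetype otherwise; the remainder draws from normal / fibrosis /
#' necrosis / artifact archetypes at fixed proportions, so patches outside
#' the tumor class carry no information about \eqn{g_i} by construction.
#' The true log hazard is the grade signal applied to the standardized
#' grade, \deqn{\eta_i = \beta \, (g_i - 1/2) / \sqrt{1/20},} i.e. `beta`
#' is the log hazard ratio per SD of latent grade (the raw-grade link
#' \eqn{\beta g_i} cannot produce strong discrimination for any plausible
#' `beta` because \eqn{g_i} is bounded in \[0, 1\]; see the vignette).
#' Survival comes from [sample_survival()].
#'
#' @param config a [cohort_config()].
#' @param archetypes optional archetype table from [default_archetypes()];
#'   by default built from the config's `embed_dim`, `separation`, `spread`.
#' @return object of class `wsi_cohort`: list with `bags` (list of
#'   `slide_bag`), `survival` (data.frame `slide_id`, `time`, `event`),
#'   `truth` (data.frame `slide_id`, `grade`, `eta`), `config`,
#'   `archetypes`, `cohort_id`.
#' @export
make_cohort <- function(config = cohort_config(), archetypes = NULL) {
  if (!inherits(config, "cohort_config")) stop_param("config must be a cohort_config")
  d <- config$embed_dim
  if (is.null(archetypes))
    archetypes <- default_archetypes(d, config$separation, config$spread,
                                     config$artifact_spread)
  means <- attr(archetypes, "means")
  if (ncol(means) != d) stop_param("archetype means have dim %d, config wants %d",
                                   ncol(means), d)
  set.seed(config$seed)
  n <- config$n_slides
  g <- stats::rbeta(n, 2, 2)
  eta <- config$beta * (g - 0.5) / sqrt(0.05)
  nt_names <- c("normal", "fibrosis", "necrosis", "artifact")
  bags <- vector("list", n)
  ids <- sprintf("slide_%03d", seq_len(n))
  for (i in seq_len(n)) {
    N <- config$patches_min +
      sample.int(config$patches_max - config$patches_min + 1L, 1L) - 1L
    n_tum <- stats::rbinom(1L, N, config$tumor_fraction)
    arche <- character(N)
    if (n_tum > 0)
      arche[seq_len(n_tum)] <- ifelse(stats::runif(n_tum) < g[i],
                                      "tumor_high", "tumor_low")
    if (N > n_tum)
      arche[(n_tum + 1L):N] <- sample(nt_names, N - n_tum, replace = TRUE,
                                      prob = config$nontumor_mix[nt_names])
    arche <- arche[sample.int(N)]            # shuffle spatial order
    sds <- archetypes$spread[match(arche, archetypes$name)]
    X <- means[arche, , drop = FALSE] +
      matrix(stats::rnorm(N * d), N, d) * sds
    side <- ceiling(sqrt(N))
    cells <- seq_len(N) - 1L
    coords <- cbind(row = cells %/% side, col = cells %% side)
    cls <- ifelse(arche %in% c("tumor_low", "tumor_high"), "tumor",
                  ifelse(arche == "artifact", "artifact", "normal"))
    bags[[i]] <- slide_bag(ids[i], X, coords, cls,
                           cohort_id = "synthetic", archetype = arche)
  }
  surv <- sample_survival(eta, config)
  surv <- data.frame(slide_id = ids, surv, stringsAsFactors = FALSE)
  truth <- data.frame(slide_id = ids, grade = g, eta = eta,
                      stringsAsFactors = FALSE)
  structure(list(bags = bags, survival = surv, truth = truth,
                 config = config, archetypes = archetypes,
                 cohort_id = "synthetic"),
            class = "wsi_cohort")
}

#' @export
print.wsi_cohort <- function(x, ...) {
  np <- vapply(x$bags, function(b) nrow(b$embeddings), 0)
  cat(sprintf("<wsi_cohort '%s'> %d slides, %d-%d patches/slide, d=%d, %.0f%% events\n",
              x$cohort_id, length(x$bags), min(np), max(np),
              x$config$embed_dim, 100 * mean(x$survival$event)))
  invisible(x)
}

#' Construct a cross-cohort domain shift
#'
#' Emulates inter-dataset distribution shift (staining protocol, scanner,
#' etiology) as an affine map of embedding space plus an optional
#' acceleration of the survival time scale. The linear part interpolates
#' between the identity and a random rotation, `A = (1-s) I + s Q`, with a
#' translation `b` of magnitude growing in `s`; `strength = 0` is the
#' identity shift, `strength = 1` scrambles embedding axes completely.
#'
#' @param d embedding dimension.
#' @param strength shift severity in \[0, 1\].
#' @param seed RNG seed for the rotation/offset.
#' @param rate_multiplier overall hazard acceleration; observed times are
#'   divided by it.
#' @return object of class `domain_shift` with fields `A`, `b`,
#'   `rate_multiplier`.
#' @export
make_domain_shift <- function(d, strength = 1, seed = 1L, rate_multiplier = 1) {
  check_number(d, "d", min = 2); check_number(strength, "strength", min = 0)
  check_number(rate_multiplier, "rate_multiplier", positive = TRUE)
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  A <- (1 - strength) * diag(d) + strength * Q
  if (abs(det(A)) < 1e-8) A <- A + 1e-3 * diag(d)
  b <- strength * stats::rnorm(d, sd = 1.5)
  domain_shift(A, b, rate_multiplier)
}

#' @rdname make_domain_shift
#' @param A invertible d x d matrix applied to every embedding.
#' @param b length-d offset.
#' @export
domain_shift <- function(A, b, rate_multiplier = 1) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_param("A must be square")
  if (length(b) != nrow(A)) stop_param("b must have length nrow(A)")
  if (abs(det(A)) < .Machine$double.eps) stop_param("A must be invertible")
  structure(list(A = A, b = as.numeric(b), rate_multiplier = rate_multiplier),
            class = "domain_shift")
}

#' Apply a domain shift to a cohort
#'
#' Every embedding x becomes `A x + b`; observed survival times are divided
#' by the shift's `rate_multiplier`. Truth labels, tissue classes and grid
#' coordinates are untouched.
#'
#' @param cohort a `wsi_cohort`.
#' @param shift a [domain_shift()].
#' @param cohort_id optional new cohort id recorded on the result.
#' @return the shifted `wsi_cohort`.
#' @export
apply_domain_shift <- function(cohort, shift, cohort_id = NULL) {
  if (!inherits(cohort, "wsi_cohort")) stop_param("cohort must be a wsi_cohort")
  if (!inherits(shift, "domain_shift")) stop_param("shift must be a domain_shift")
  d <- cohort$config$embed_dim
  if (nrow(shift$A) != d)
    stop_param("shift dimension %d does not match embedding dim %d",
               nrow(shift$A), d)
  new_id <- cohort_id %||% paste0(cohort$cohort_id, "_shifted")
  cohort$bags <- lapply(cohort$bags, function(b) {
    b$embeddings <- b$embeddings %*% t(shift$A) +
      matrix(shift$b, nrow(b$embeddings), d, byrow = TRUE)
    b$cohort_id <- new_id
    b
  })
  cohort$survival$time <- cohort$survival$time / shift$rate_multiplier
  cohort$cohort_id <- new_id
  cohort
}

#' Synthetic tissue-QC tiles
#'
#' Generates small grayscale rasters emulating the tissue vs non-tissue
#' patch classification problem: half the tiles are textured "tissue"
#' (speckle noise plus dark nucleus-like blobs), half are "non_tissue"
#' artifacts cycling through three subtypes — near-uniform bright
#' background, saturated marker ink, and heavy out-of-focus blur.
#' Background subtypes have per-tile intensity variance far below any
#' tissue tile. Intensities are clipped to \[0, 1\].
#'
#' @param n even tile count (>= 2); half per class.
#' @param seed RNG seed.
#' @param size tile side in pixels; the default 36 matches the QC network's
#'   input (three 5x5 valid convolutions with 2x2 poolings reduce 36 to 1).
#' @return list with `tiles` (n x size x size array), `labels` (factor
#'   `tissue`/`non_tissue`) and `subtype` (character per tile).
#' @export
make_qc_tiles <- function(n, seed = 1L, size = 36L) {
  check_number(n, "n", min = 2)
  if (n %% 2 != 0) stop_param("n must be even (balanced classes)")
  set.seed(seed)
  tiles <- array(0, c(n, size, size))
  labels <- rep(c("tissue", "non_tissue"), each = n / 2)
  subtype <- ifelse(labels == "tissue", "texture",
                    c("background", "marker", "blur")[(seq_len(n) %% 3) + 1])
  for (i in seq_len(n)) tiles[i, , ] <- render_qc_tile(subtype[i], size)
  perm <- sample.int(n)
  list(tiles = tiles[perm, , , drop = FALSE],
       labels = factor(labels[perm], levels = c("non_tissue", "tissue")),
       subtype = subtype[perm])
}

# One synthetic QC tile; `kind` is texture (tissue) or one of the three
# artifact subtypes. Uses the current RNG stream.
render_qc_tile <- function(kind, size = 36L) {
  px <- seq_len(size)
  img <- switch(kind,
    texture = {
      im <- matrix(0.55 + stats::rnorm(size^2, sd = 0.12), size, size)
      for (k in seq_len(sample(6:12, 1))) {   # nucleus-like dark blobs
        cx <- stats::runif(1, 4, size - 3); cy <- stats::runif(1, 4, size - 3)
        rad <- stats::runif(1, 1.2, 2.5)
        im <- im - 0.35 * exp(-(outer((px - cx)^2, (px - cy)^2, "+")) /
                                (2 * rad^2))
      }
      im
    },
    background = matrix(0.95 + stats::rnorm(size^2, sd = 0.004), size, size),
    marker = matrix(stats::runif(1, 0.15, 0.35) +
                      stats::rnorm(size^2, sd = 0.003), size, size),
    blur = {
      fx <- stats::runif(2, 0.5, 1.5); ph <- stats::runif(2, 0, 2 * pi)
      0.7 + 0.05 * outer(sin(2 * pi * fx[1] * px / size + ph[1]),
                         sin(2 * pi * fx[2] * px / size + ph[2])) +
        matrix(stats::rnorm(size^2, sd = 0.003), size, size)
    },
    stop_param("unknown tile kind '%s'", kind))
  pmin(pmax(img, 0), 1)
}
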