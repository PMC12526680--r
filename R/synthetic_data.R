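# The 22 crop labels of the standard crop-recommendation schema, used as
# default label names by the synthetic generator and the shipped kb.
CROP_LABELS_22 <- c(
  "apple", "banana", "blackgram", "chickpea", "coconut", "coffee", "cotton",
  "grapes", "jute", "kidneybeans", "lentil", "maize", "mango", "mothbeans",
  "mungbean", "muskmelon", "orange", "papaya", "pigeonpeas", "pomegranate",
  "rice", "watermelon")

# Plausible physical ranges for the non-physics features; class centres and
# within-class spreads are expressed relative to these.
FEATURE_RANGES <- list(
  N = c(0, 140), P = c(5, 145), K = c(5, 205),
  humidity = c(14, 100), rainfall = c(20, 300))

# Inverse-CDF truncated normal: base-R only, deterministic under set.seed.
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n)
  x <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  pmin(pmax(x, lo), hi)
}

# Deterministic per-class sub-stream seed (kept below 2^31).
class_seed <- function(seed, j) {
  (abs(seed) %% 100000L) * 1009L + 7919L * j %% 2147483647L
}

#' Synthetic-data generator configuration
#'
#' Defaults mirror the benchmark dataset the method targets: 22 balanced
#' classes with 100 samples each (2200 rows, 7 features). `separation`
#' controls between-class distance of the non-physics features (N, P, K,
#' humidity, rainfall), `noise_scale` their within-class spread, and
#' `physics_fidelity` the within-class temperature/pH spread as a multiple of
#' the knowledge-base sigma.
#'
#' @param n_classes number of crop classes (>= 2).
#' @param samples_per_class rows generated per class.
#' @param separation positive multiplier on between-class centre spread.
#' @param noise_scale positive multiplier on within-class feature spread.
#' @param physics_fidelity positive multiple of the kb sigma used as the
#'   within-class temperature/pH standard deviation.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 22, samples_per_class = 100,
                             separation = 3, noise_scale = 1,
                             physics_fidelity = 1, seed = 42) {
  stopifnot(n_classes >= 2, samples_per_class >= 1, separation > 0,
            noise_scale > 0, physics_fidelity > 0)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 separation = separation, noise_scale = noise_scale,
                 physics_fidelity = physics_fidelity,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a default knowledge base for synthetic experiments
#'
#' Spreads crop temperature optima over 15-35 °C and pH optima over 5.0-7.5
#' (an agronomically plausible range), on an even grid with a small seeded
#' jitter and a seeded assignment of grid positions to labels. Deterministic
#' for a fixed seed. For `n_classes <= 22` the standard crop names are used;
#' beyond that, labels are `crop_01`, `crop_02`, ...
#'
#' @param n_classes number of crops (>= 2).
#' @param seed integer RNG seed.
#' @return a [crop_kb].
#' @export
make_default_knowledge_base <- function(n_classes = 22, seed = 42) {
  stopifnot(n_classes >= 2)
  labels <- if (n_classes <= length(CROP_LABELS_22)) {
    sort(CROP_LABELS_22)[seq_len(n_classes)]
  } else {
    sprintf("crop_%03d", seq_len(n_classes))
  }
  set.seed(class_seed(seed, 0L))
  grid_t <- seq(15, 35, length.out = n_classes)
  grid_p <- seq(5.0, 7.5, length.out = n_classes)
  jit_t <- stats::runif(n_classes, -0.3, 0.3) * (20 / n_classes)
  jit_p <- stats::runif(n_classes, -0.3, 0.3) * (2.5 / n_classes)
  # independent permutations so temperature rank does not dictate pH rank
  perm_t <- sample(n_classes)
  perm_p <- sample(n_classes)
  entries <- data.frame(
    label = labels,
    mu_temp = pmin(pmax(grid_t[perm_t] + jit_t, 15), 35),
    sigma_temp = stats::runif(n_classes, 1.5, 3.0),
    mu_ph = pmin(pmax(grid_p[perm_p] + jit_p, 5.0), 7.5),
    sigma_ph = stats::runif(n_classes, 0.3, 0.6),
    stringsAsFactors = FALSE)
  crop_kb(entries)
}

#' Generate a class-conditional synthetic crop dataset
#'
#' For each crop class c: temperature ~ Normal(mu_temp_c,
#' physics_fidelity * sigma_temp_c); pH ~ the same construction truncated to
#' \[0, 14\]; N, P, K, humidity and rainfall ~ class-specific truncated
#' Normals whose centres are drawn once per dataset and spread proportionally
#' to `separation`, with within-class standard deviation proportional to
#' `noise_scale`. Exactly `samples_per_class` rows per class; fully
#' deterministic for a fixed seed (one dataset-level stream for the class
#' centres, one derived sub-stream per class for the draws).
#'
#' @param config a [synthetic_config].
#' @param kb a [crop_kb] covering at least `n_classes` labels; defaults to
#'   [make_default_knowledge_base] under the config seed.
#' @return a [crop_dataset] with `n_classes * samples_per_class` rows.
#' @export
generate_crops <- function(config = synthetic_config(), kb = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(kb)) kb <- make_default_knowledge_base(config$n_classes,
                                                     config$seed)
  C <- config$n_classes
  if (length(kb$class_order) < C) {
    stop("knowledge base covers ", length(kb$class_order),
         " crops but n_classes = ", C, call. = FALSE)
  }
  labels <- kb$class_order[seq_len(C)]
  cov <- validate_coverage(kb, labels)
  if (!cov$ok) {
    stop("knowledge base does not cover: ",
         paste(cov$uncovered, collapse = ", "), call. = FALSE)
  }
  m <- config$samples_per_class

  # dataset-level stream: class centres of the non-physics features
  set.seed(class_seed(config$seed, 0L))
  centres <- sapply(names(FEATURE_RANGES), function(f) {
    r <- FEATURE_RANGES[[f]]
    mid <- mean(r); unit <- diff(r) / 6
    mid + config$separation * (stats::runif(C) - 0.5) * unit
  })
  centres <- matrix(centres, nrow = C,
                    dimnames = list(NULL, names(FEATURE_RANGES)))

  out <- vector("list", C)
  for (j in seq_len(C)) {
    e <- kb$entries[match(labels[j], kb$entries$label), ]
    set.seed(class_seed(config$seed, j))
    block <- data.frame(row.names = seq_len(m))
    for (f in names(FEATURE_RANGES)) {
      r <- FEATURE_RANGES[[f]]
      sdev <- config$noise_scale * diff(r) / 20
      lo <- 0
      hi <- if (f == "humidity") 100 else Inf
      block[[f]] <- rtnorm(m, centres[j, f], sdev, lo, hi)
    }
    block$temperature <- stats::rnorm(
      m, e$mu_temp, config$physics_fidelity * e$sigma_temp)
    block$ph <- rtnorm(m, e$mu_ph, config$physics_fidelity * e$sigma_ph,
                       0, 14)
    block$label <- labels[j]
    out[[j]] <- block[, c(CROP_FEATURES, "label")]
  }
  crop_dataset(do.call(rbind, out), class_order = sort(labels))
}

#' Corrupt a dataset with label and feature noise
#'
#' Flips `round(label_noise * n)` labels (chosen uniformly under the seed) to
#' a uniformly random *other* class and adds zero-mean Gaussian noise, scaled
#' by `feature_noise` times each feature's empirical standard deviation, to
#' the non-physics features (N, P, K, humidity, rainfall). Temperature and pH
#' are never perturbed, so the physics signal is preserved. With both knobs
#' at zero the input is returned unchanged.
#'
#' @param data a `crop_dataset`.
#' @param label_noise fraction of labels to flip, in \[0, 1).
#' @param feature_noise non-negative noise multiplier.
#' @param seed integer RNG seed.
#' @return a corrupted `crop_dataset`.
#' @export
corrupt_dataset <- function(data, label_noise = 0, feature_noise = 0,
                            seed = 1) {
  stopifnot(label_noise >= 0, label_noise < 1, feature_noise >= 0)
  if (label_noise == 0 && feature_noise == 0) return(data)
  df <- data$df
  n <- nrow(df)
  set.seed(class_seed(seed, 0L))
  if (label_noise > 0) {
    n_flip <- round(label_noise * n)
    flip <- sample(n, n_flip)
    for (i in flip) {
      others <- setdiff(data$class_order, df$label[i])
      df$label[i] <- others[sample.int(length(others), 1)]
    }
  }
  if (feature_noise > 0) {
    for (f in names(FEATURE_RANGES)) {
      sdev <- stats::sd(df[[f]])
      x <- df[[f]] + stats::rnorm(n, 0, feature_noise * sdev)
      x <- pmax(x, 0)
      if (f == "humidity") x <- pmin(x, 100)
      df[[f]] <- x
    }
  }
  crop_dataset(df, class_order = data$class_order)
}
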