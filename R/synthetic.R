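# Synthetic cohort generators.  These define the study conditions every
# pipeline stage is tested under: a training cohort shaped like the
# published 240-sample reference (73 ABC / 115 GCB / 52 Type-III), probe
# structure exercising both collapse rules, survival with a planted class
# hazard effect, and signature databases with planted positives.

#' Specify a synthetic cohort
#'
#' Defaults emulate the reference training cohort: 240 samples in
#' proportions 73/115/52 over ABC/GCB/Type-III, the shipped classifier-gene
#' panel shifted by +/-1.5 sd by class with Type-III attenuated at 0.3 sd
#' (the "molecular gray zone"), replicate probes correlated at 0.8 with a
#' 10% decoy-probe fraction at correlation 0, and unit-sd noise on an
#' arbitrary intensity baseline.
#'
#' @param n_samples cohort size.
#' @param class_proportions named proportions over ABC/GCB/TYPE_III
#'   (must sum to 1).
#' @param classifier_genes data.frame `gene`, `class` as from
#'   [dac_classifier_genes()].
#' @param shift class mean shift of classifier genes, in noise-sd units.
#' @param type3_shift attenuated shift of Type-III samples.
#' @param n_noise_genes exchangeable uninformative genes.
#' @param probe_multiplicity probabilities of 1, 2, ... probes per gene.
#' @param probe_cor target Pearson correlation of replicate probes.
#' @param decoy_fraction fraction of extra probes carrying no signal.
#' @param noise_sd per-gene biological + technical noise sd.
#' @param baseline additive intensity offset keeping values positive.
#' @param seed integer seed; recorded in every artifact.
#' @return `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 240L,
                        class_proportions = c(ABC = 73, GCB = 115,
                                              TYPE_III = 52) / 240,
                        classifier_genes = dac_classifier_genes(),
                        shift = 1.5, type3_shift = 0.3,
                        n_noise_genes = 480L,
                        probe_multiplicity = c(0.6, 0.3, 0.1),
                        probe_cor = 0.8, decoy_fraction = 0.1,
                        noise_sd = 1, baseline = 8, seed = 0L) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  structure(list(n_samples = as.integer(n_samples),
                 class_proportions = class_proportions[DAC_CLASSES],
                 classifier_genes = classifier_genes, shift = shift,
                 type3_shift = type3_shift,
                 n_noise_genes = as.integer(n_noise_genes),
                 probe_multiplicity = probe_multiplicity,
                 probe_cor = probe_cor, decoy_fraction = decoy_fraction,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# largest-remainder apportionment of n over proportions
class_counts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# per-sample class mean of one classifier gene
gene_class_means <- function(gene_class, labels, shift, type3_shift) {
  m <- numeric(length(labels))
  other <- if (gene_class == "ABC") "GCB" else "ABC"
  m[labels == gene_class] <- shift
  m[labels == other] <- -shift
  m[labels == "TYPE_III"] <- type3_shift
  m
}

#' Simulate a probe-level cohort with planted class structure
#'
#' Classifier genes are shifted by class (up in their own class, down in
#' the opposite one, weakly up in Type-III); noise genes are exchangeable.
#' Each gene gets 1 or more probes: replicate probes share the gene signal
#' plus independent noise calibrated to the requested correlation, and a
#' fraction of decoy probes carry no signal (correlation 0), exercising
#' both branches of the max/average collapse rule.  Deterministic given the
#' spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list `expression` (probe-level [expression_matrix()]),
#'   `probe_map` (named character: probe -> gene), `labels` (true classes),
#'   `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  counts <- class_counts(n, spec$class_proportions)
  labels <- sample(rep(DAC_CLASSES, counts))
  genes <- c(spec$classifier_genes$gene,
             sprintf("NOISE%04d", seq_len(spec$n_noise_genes)))
  gclass <- c(spec$classifier_genes$class,
              rep("none", spec$n_noise_genes))
  probe_rows <- list()
  probe_map <- character(0)
  tau <- spec$noise_sd * sqrt(max(1 / spec$probe_cor - 1, 0))
  for (i in seq_along(genes)) {
    mu <- if (gclass[i] %in% c("ABC", "GCB"))
      gene_class_means(gclass[i], labels, spec$shift, spec$type3_shift)
    else numeric(n)
    signal <- spec$baseline + mu + rnorm(n, 0, spec$noise_sd)
    m <- sample.int(length(spec$probe_multiplicity), 1L,
                    prob = spec$probe_multiplicity)
    for (j in seq_len(m)) {
      decoy <- j > 1L && runif(1) < spec$decoy_fraction
      val <- if (decoy) spec$baseline + rnorm(n, 0, spec$noise_sd)
             else if (m == 1L) signal
             else signal + rnorm(n, 0, tau)
      pid <- sprintf("%s_p%d", genes[i], j)
      probe_rows[[pid]] <- val
      probe_map[pid] <- genes[i]
    }
  }
  vals <- do.call(rbind, probe_rows)
  colnames(vals) <- sprintf("SAMPLE_%03d", seq_len(n))
  list(expression = expression_matrix(vals, level = "PROBE",
                                      platform = "synthetic"),
       probe_map = probe_map,
       labels = setNames(labels, colnames(vals)),
       spec = spec)
}

#' Simulate right-censored survival with a planted class effect
#'
#' Exponential event times with class-specific rates: ABC at the baseline
#' rate, GCB at `baseline_rate * hr_gcb_vs_abc`, Type-III at the geometric
#' mean of the two.  Censoring is independent exponential with its rate
#' solved so each case is censored with probability `censor_rate`.
#'
#' @param labels named class vector (names = sample ids).
#' @param hr_gcb_vs_abc planted hazard ratio of GCB relative to ABC (> 0).
#' @param baseline_rate ABC event rate (1 / time unit).
#' @param censor_rate target censoring probability in `[0, 1)`.
#' @param seed integer seed.
#' @return data.frame `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(labels, hr_gcb_vs_abc = 0.4,
                              baseline_rate = 0.1, censor_rate = 0.2,
                              seed = 0L) {
  stopifnot(hr_gcb_vs_abc > 0, censor_rate >= 0, censor_rate < 1)
  set.seed(seed)
  rate <- baseline_rate *
    c(ABC = 1, GCB = hr_gcb_vs_abc,
      TYPE_III = sqrt(hr_gcb_vs_abc))[as.character(labels)]
  t_event <- rexp(length(rate), rate)
  if (censor_rate > 0) {
    c_rate <- rate * censor_rate / (1 - censor_rate)
    t_cens <- rexp(length(rate), c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, length(rate))
    time <- t_event
  }
  data.frame(sample_id = names(labels) %||% paste0("S", seq_along(rate)),
             time = time, event = event,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a gene-signature database
#'
#' Planted signatures sample mostly (by default 80%) from a supplied
#' profile, giving designed positive controls; random signatures sample
#' uniformly from the population as null controls.
#'
#' @param population character vector of all genes.
#' @param planted_from_profile profile genes the planted signatures draw
#'   from (`NULL` for none).
#' @param n_planted number of planted signatures.
#' @param n_random_sigs number of random signatures.
#' @param size_range inclusive signature-size range.
#' @param in_profile_frac fraction of a planted signature drawn from the
#'   profile.
#' @param seed integer seed.
#' @return list of `list(name, source, genes)`, writable with
#'   [write_gmt()].
#' @export
simulate_signature_db <- function(population, planted_from_profile = NULL,
                                  n_planted = 5L, n_random_sigs = 100L,
                                  size_range = c(20L, 100L),
                                  in_profile_frac = 0.8, seed = 0L) {
  if (length(population) < max(size_range))
    stop("population smaller than the largest signature size")
  set.seed(seed)
  sizes <- function(k) if (size_range[1] == size_range[2])
    rep(size_range[1], k) else
    sample(size_range[1]:size_range[2], k, replace = TRUE)
  out <- list()
  if (!is.null(planted_from_profile) && n_planted > 0) {
    for (i in seq_len(n_planted)) {
      sz <- sizes(1L)
      n_in <- min(round(in_profile_frac * sz), length(planted_from_profile))
      g <- unique(c(sample(planted_from_profile, n_in),
                    sample(setdiff(population, planted_from_profile),
                           sz - n_in)))
      out[[sprintf("PLANTED_%03d", i)]] <-
        list(name = sprintf("PLANTED_%03d", i), source = "synthetic",
             genes = g)
    }
  }
  for (i in seq_len(n_random_sigs))
    out[[sprintf("RANDOM_%03d", i)]] <-
      list(name = sprintf("RANDOM_%03d", i), source = "synthetic",
           genes = sample(population, sizes(1L)))
  out
}

#' Simulate a multi-dataset collection with a shared class-gene core
#'
#' Generates `n_datasets` gene-level cohorts sharing planted ABC-up and
#' GCB-up gene cores (the meta-profile ground truth) on top of the
#' classifier-gene structure of [simulate_cohort()], with per-dataset
#' effect-size jitter and optional per-platform gene dropout (classifier
#' genes are never dropped, so every data set remains classifiable).
#'
#' @param n_datasets number of data sets (>= 2).
#' @param n_core_abc,n_core_gcb planted always-class-associated genes.
#' @param n_samples samples per data set.
#' @param n_noise_genes uninformative genes per data set.
#' @param effect class effect of core genes (sd units, log2-like scale).
#' @param per_dataset_jitter sd of the multiplicative effect jitter.
#' @param dropout per-dataset probability that a non-classifier gene is
#'   absent from the platform.
#' @param class_proportions proportions over ABC/GCB/TYPE_III.
#' @param seed integer seed.
#' @return list with `datasets` (each: `expression` gene-level
#'   [expression_matrix()], `labels`, `platform` gene vector) and `truth`
#'   (`abc_core`, `gcb_core` gene names).
#' @export
simulate_multidataset <- function(n_datasets = 11L, n_core_abc = 30L,
                                  n_core_gcb = 30L, n_samples = 100L,
                                  n_noise_genes = 400L, effect = 1.2,
                                  per_dataset_jitter = 0.15, dropout = 0,
                                  class_proportions = c(ABC = 0.35,
                                                        GCB = 0.45,
                                                        TYPE_III = 0.2),
                                  seed = 0L) {
  if (n_datasets < 2L) stop("need >= 2 data sets")
  panel <- dac_classifier_genes()
  abc_core <- sprintf("CORE_ABC_%03d", seq_len(n_core_abc))
  gcb_core <- sprintf("CORE_GCB_%03d", seq_len(n_core_gcb))
  noise <- sprintf("NOISE%04d", seq_len(n_noise_genes))
  genes <- c(panel$gene, abc_core, gcb_core, noise)
  gclass <- c(panel$class, rep("ABC", n_core_abc), rep("GCB", n_core_gcb),
              rep("none", n_noise_genes))
  core <- genes %in% c(abc_core, gcb_core)
  datasets <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(seed + 1000L * d)
    keepable <- !(genes %in% panel$gene)
    drop <- keepable & runif(length(genes)) < dropout
    platform <- genes[!drop]
    counts <- class_counts(n_samples, class_proportions[DAC_CLASSES])
    labels <- sample(rep(DAC_CLASSES, counts))
    names(labels) <- sprintf("D%02d_S%03d", d, seq_len(n_samples))
    vals <- matrix(rnorm(length(platform) * n_samples, 0, 1),
                   length(platform), n_samples,
                   dimnames = list(platform, names(labels)))
    for (i in seq_along(platform)) {
      g <- platform[i]
      gi <- match(g, genes)
      if (gclass[gi] == "none") next
      eff <- if (core[gi])
        effect * max(0.2, 1 + rnorm(1, 0, per_dataset_jitter))
      else 1.5  # classifier genes keep the cohort-spec shift
      t3 <- if (core[gi]) 0 else 0.3
      vals[i, ] <- vals[i, ] +
        gene_class_means(gclass[gi], labels, eff, t3)
    }
    vals <- vals + 8
    datasets[[d]] <- list(
      expression = expression_matrix(vals, level = "GENE",
                                     platform = sprintf("synthetic_%02d", d)),
      labels = labels, platform = platform)
  }
  names(datasets) <- sprintf("DS%02d", seq_len(n_datasets))
  list(datasets = datasets,
       truth = list(abc_core = abc_core, gcb_core = gcb_core))
}
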