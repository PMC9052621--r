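# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its spec (seed included): the global RNG stream is saved
# and restored around each call.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Specification for a simulated single-cell dataset
#'
#' Describes one synthetic scRNA-seq dataset with a latent differentiation
#' gradient. Every cell carries a latent differentiation value `d` in
#' \[0, 1\] (1 = most stem-like). Library complexity — the number of
#' detectably expressed genes — increases with `d` through a per-cell scaling
#' of expected counts (`gradient_strength`), so the gene-counts/stemness
#' association emerges mechanistically rather than by construction. Three
#' planted gene classes probe the signature derivation:
#' `stem` genes rise with `d` in malignant cells *and* are malignant-
#' upregulated (true signal); `decoy_stem` genes rise with `d` in all cells
#' equally (stemness-correlated but not tumor-specific); `decoy_de` genes
#' are malignant-upregulated but flat in `d`.
#'
#' @param n_cells,n_genes Dataset dimensions.
#' @param malignant_fraction Fraction of cells flagged malignant, in (0, 1].
#' @param n_stem_genes,n_decoy_stem_genes,n_decoy_de_genes Planted gene
#'   counts per class.
#' @param gradient_strength Log-scale slope of the per-cell complexity
#'   factor in `d` (0 switches the gradient off).
#' @param stem_effect Log-scale slope in `d` for stem / decoy_stem genes.
#' @param de_lfc Natural-log malignant-vs-other fold change for stem /
#'   decoy_de genes.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param base_mean,planted_mean Baseline mean counts for background and
#'   planted genes.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A `scrna_sim_spec` list.
#' @export
scrna_sim_spec <- function(n_cells = 2000, n_genes = 1500,
                           malignant_fraction = 0.7,
                           n_stem_genes = 20, n_decoy_stem_genes = 20,
                           n_decoy_de_genes = 20,
                           gradient_strength = 1, stem_effect = 2,
                           de_lfc = 1, dispersion = 0.5,
                           base_mean = 0.5, planted_mean = 1.5,
                           seed = 1L) {
  stopifnot(
    n_cells > 0, n_genes > 0,
    n_stem_genes >= 0, n_decoy_stem_genes >= 0, n_decoy_de_genes >= 0,
    gradient_strength >= 0, dispersion > 0
  )
  if (malignant_fraction <= 0 || malignant_fraction > 1) {
    stop("malignant_fraction must be in (0, 1]: signature derivation requires malignant cells",
         call. = FALSE)
  }
  if (n_stem_genes + n_decoy_stem_genes + n_decoy_de_genes > n_genes) {
    stop("planted genes exceed n_genes", call. = FALSE)
  }
  structure(
    list(
      n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
      malignant_fraction = malignant_fraction,
      n_stem_genes = as.integer(n_stem_genes),
      n_decoy_stem_genes = as.integer(n_decoy_stem_genes),
      n_decoy_de_genes = as.integer(n_decoy_de_genes),
      gradient_strength = gradient_strength, stem_effect = stem_effect,
      de_lfc = de_lfc, dispersion = dispersion,
      base_mean = base_mean, planted_mean = planted_mean,
      seed = as.integer(seed)
    ),
    class = "scrna_sim_spec"
  )
}

simulate_scrna_dataset <- function(spec) {
  with_seed(spec$seed, {
    n_c <- spec$n_cells
    n_g <- spec$n_genes
    cell_ids <- sprintf("cell%05d", seq_len(n_c))
    gene_ids <- sprintf("G%04d", seq_len(n_g))

    n_mal <- max(1L, round(spec$malignant_fraction * n_c))
    malignant <- seq_len(n_c) <= n_mal
    d <- runif(n_c)

    classes <- rep("neutral", n_g)
    idx <- 0
    stem_idx <- seq_len(spec$n_stem_genes)
    classes[stem_idx] <- "stem"
    idx <- spec$n_stem_genes
    dstem_idx <- idx + seq_len(spec$n_decoy_stem_genes)
    classes[dstem_idx] <- "decoy_stem"
    idx <- idx + spec$n_decoy_stem_genes
    dde_idx <- idx + seq_len(spec$n_decoy_de_genes)
    classes[dde_idx] <- "decoy_de"

    base <- rlnorm(n_g, meanlog = log(spec$base_mean), sdlog = 1)
    planted <- classes != "neutral"
    base[planted] <- rlnorm(sum(planted), meanlog = log(spec$planted_mean),
                            sdlog = 0.3)

    # log-scale expected counts, cells x genes
    eta <- matrix(log(base), nrow = n_c, ncol = n_g, byrow = TRUE)
    comp <- spec$gradient_strength * (d - 0.5) # per-cell complexity factor
    eta <- eta + comp
    dd <- spec$stem_effect * (d - 0.5)
    if (length(stem_idx)) {
      eta[malignant, stem_idx] <- eta[malignant, stem_idx] + dd[malignant]
      eta[malignant, stem_idx] <- eta[malignant, stem_idx] + spec$de_lfc
    }
    if (length(dstem_idx)) {
      eta[, dstem_idx] <- eta[, dstem_idx] + dd
    }
    if (length(dde_idx)) {
      eta[malignant, dde_idx] <- eta[malignant, dde_idx] + spec$de_lfc
    }

    counts <- matrix(
      rnbinom(n_c * n_g, mu = exp(eta), size = 1 / spec$dispersion),
      nrow = n_c, ncol = n_g, dimnames = list(cell_ids, gene_ids)
    )

    structure(
      list(
        counts = expr_mat(counts, layer_tag = "raw_counts",
                          orientation = "cell_by_gene"),
        malignant = setNames(malignant, cell_ids),
        latent_d = setNames(d, cell_ids),
        truth = tibble::tibble(gene = gene_ids, class = classes),
        spec = spec
      ),
      class = "scrna_dataset"
    )
  })
}

#' Simulate a panel of single-cell datasets
#'
#' Generates one [scrna_sim_spec()]-described dataset per spec, emulating a
#' multi-dataset pan-cancer single-cell panel. Each dataset comes with its
#' truth table (planted class per gene) so precision/recall of every
#' downstream discovery step can be computed without re-deriving labels.
#'
#' @param specs A list of [scrna_sim_spec()] objects (distinct seeds
#'   recommended), or a single spec.
#' @return A list of `scrna_dataset` objects, each with elements `counts`
#'   (an [expr_mat()], cells x genes, raw counts), `malignant` (named
#'   logical), `latent_d` (named numeric), `truth` (tibble), `spec`.
#' @export
simulate_scrna_panel <- function(specs) {
  if (inherits(specs, "scrna_sim_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  lapply(specs, function(s) {
    stopifnot(inherits(s, "scrna_sim_spec"))
    simulate_scrna_dataset(s)
  })
}

#' Specification for simulated bulk immunotherapy cohorts
#'
#' Describes a multi-cohort bulk expression study on a log-like scale:
#' a per-sample responder label, a mean shift of the signature genes in
#' non-responders (`effect_size`; stemness is expected to be higher where
#' therapy fails), additive per-batch per-gene offsets, and exponential
#' overall survival whose hazard is multiplied by `hazard_ratio` in the
#' high-risk (non-responder) group, with administrative censoring.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param signature_genes Character vector of genes carrying the
#'   response-associated shift (non-empty).
#' @param effect_size Mean shift of signature genes in non-responders,
#'   log-scale units.
#' @param responder_fraction Probability a sample is a responder, in (0, 1).
#' @param n_batches,batch_sd Number of cohorts/batches and the SD of their
#'   additive per-gene offsets.
#' @param hazard_ratio Hazard multiplier, high-risk vs low-risk (> 0).
#' @param median_os_low Median overall survival of the low-risk group,
#'   months.
#' @param censor_horizon Administrative censoring horizon, months.
#' @param seed Integer seed.
#' @return A `bulk_sim_spec` list.
#' @export
bulk_sim_spec <- function(n_samples = 600, n_genes = 1000,
                          signature_genes = sprintf("G%04d", 1:25),
                          effect_size = 0.8, responder_fraction = 0.35,
                          n_batches = 3, batch_sd = 0.5,
                          hazard_ratio = 2, median_os_low = 25,
                          censor_horizon = 36, seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1, length(signature_genes) >= 1,
            hazard_ratio > 0, batch_sd >= 0, median_os_low > 0,
            censor_horizon > 0)
  if (responder_fraction <= 0 || responder_fraction >= 1) {
    stop("responder_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_batches < 1) {
    stop("n_batches must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      signature_genes = as.character(signature_genes),
      effect_size = effect_size, responder_fraction = responder_fraction,
      n_batches = as.integer(n_batches), batch_sd = batch_sd,
      hazard_ratio = hazard_ratio, median_os_low = median_os_low,
      censor_horizon = censor_horizon, seed = as.integer(seed)
    ),
    class = "bulk_sim_spec"
  )
}

#' Simulate bulk immunotherapy cohorts
#'
#' @param spec A [bulk_sim_spec()].
#' @return A list with `expr` (an [expr_mat()], genes x samples, lognorm
#'   layer), `clinical` (tibble: sample_id, response_raw, response_binary,
#'   os_time, os_event, tmb, batch) and `truth` (tibble: sample_id,
#'   responder, high_risk).
#' @export
simulate_bulk_cohorts <- function(spec) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
    missing_sig <- setdiff(spec$signature_genes, gene_ids)
    gene_ids <- c(gene_ids[!gene_ids %in% spec$signature_genes],
                  spec$signature_genes)
    gene_ids <- gene_ids[seq_len(spec$n_genes)]
    if (!all(spec$signature_genes %in% gene_ids)) {
      stop("signature_genes do not fit in the gene universe", call. = FALSE)
    }
    sample_ids <- sprintf("S%04d", seq_len(n))

    responder <- rbinom(n, 1, spec$responder_fraction) == 1
    batch <- sprintf("batch%d", sample(seq_len(spec$n_batches), n,
                                       replace = TRUE))

    mu <- rnorm(spec$n_genes, mean = 5, sd = 1.5)
    x <- matrix(rnorm(spec$n_genes * n, mean = mu, sd = 1),
                nrow = spec$n_genes, ncol = n,
                dimnames = list(gene_ids, sample_ids))
    sig_rows <- match(spec$signature_genes, gene_ids)
    x[sig_rows, !responder] <- x[sig_rows, !responder] + spec$effect_size
    if (spec$batch_sd > 0) {
      for (b in unique(batch)) {
        off <- rnorm(spec$n_genes, 0, spec$batch_sd)
        x[, batch == b] <- x[, batch == b] + off
      }
    }

    high_risk <- !responder
    rate0 <- log(2) / spec$median_os_low
    rate <- rate0 * ifelse(high_risk, spec$hazard_ratio, 1)
    t_event <- rexp(n, rate)
    os_time <- pmin(t_event, spec$censor_horizon)
    os_event <- as.integer(t_event <= spec$censor_horizon)

    response_raw <- ifelse(
      responder,
      ifelse(runif(n) < 0.3, "CR", "PR"),
      ifelse(runif(n) < 0.4, "SD", "PD")
    )
    clinical <- tibble::tibble(
      sample_id = sample_ids,
      response_raw = response_raw,
      response_binary = response_to_binary(response_raw),
      os_time = os_time,
      os_event = os_event,
      tmb = rlnorm(n, meanlog = log(5), sdlog = 0.8),
      batch = batch
    )
    list(
      expr = expr_mat(x, layer_tag = "lognorm",
                      orientation = "gene_by_sample"),
      clinical = clinical,
      truth = tibble::tibble(sample_id = sample_ids, responder = responder,
                             high_risk = high_risk)
    )
  })
}

#' Specification for a simulated CRISPR screen panel
#'
#' Gene x dataset normalized z-scores: neutral genes draw from N(0, 1),
#' planted immune-resistance genes from N(`resistor_effect`, 1) with
#' `resistor_effect` < 0 (knockout improves immune killing), and entries go
#' missing independently with probability `missing_fraction` (screens do not
#' all cover the same gene universe).
#'
#' @param n_genes,n_datasets Panel dimensions.
#' @param resistor_genes Character vector of planted resistor gene ids
#'   (must lie in the `G%05d` universe of `n_genes` genes).
#' @param resistor_effect Mean z of resistor entries (< 0).
#' @param missing_fraction Independent missingness probability, in \[0, 1).
#' @param seed Integer seed.
#' @return A `crispr_sim_spec` list.
#' @export
crispr_sim_spec <- function(n_genes = 5000, n_datasets = 17,
                            resistor_genes = sprintf("G%05d", 1:20),
                            resistor_effect = -2, missing_fraction = 0.3,
                            seed = 1L) {
  stopifnot(n_genes >= 1, n_datasets >= 1)
  universe <- sprintf("G%05d", seq_len(n_genes))
  if (!all(resistor_genes %in% universe)) {
    stop("resistor_genes must lie in the simulated gene universe",
         call. = FALSE)
  }
  if (resistor_effect >= 0) {
    stop("resistor_effect must be negative (lower z = stronger immune sensitization on knockout)",
         call. = FALSE)
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_datasets = as.integer(n_datasets),
         resistor_genes = as.character(resistor_genes),
         resistor_effect = resistor_effect,
         missing_fraction = missing_fraction, seed = as.integer(seed)),
    class = "crispr_sim_spec"
  )
}

#' Simulate a CRISPR screen z-score panel
#'
#' @param spec A [crispr_sim_spec()].
#' @return A list with `panel` (a [crispr_panel()] with NA at masked
#'   entries) and `truth` (tibble: gene, is_resistor).
#' @export
simulate_crispr_panel <- function(spec) {
  stopifnot(inherits(spec, "crispr_sim_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    datasets <- sprintf("screen%02d", seq_len(spec$n_datasets))
    z <- matrix(rnorm(spec$n_genes * spec$n_datasets),
                nrow = spec$n_genes,
                dimnames = list(genes, datasets))
    res <- genes %in% spec$resistor_genes
    z[res, ] <- z[res, ] + spec$resistor_effect
    if (spec$missing_fraction > 0) {
      mask <- matrix(runif(length(z)) < spec$missing_fraction,
                     nrow = nrow(z), dimnames = dimnames(z))
      z[mask] <- NA_real_
    }
    list(
      panel = crispr_panel(z),
      truth = tibble::tibble(gene = genes, is_resistor = res)
    )
  })
}
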