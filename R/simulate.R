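# Synthetic-data generator. Emulates the statistical structure the pipeline
# assumes: replicated negative-binomial counts for the four groups
# {cytoplasmic, polysomal} x {NT, T}, with per-gene transcriptional
# log2 fold-changes and translational-efficiency shifts drawn from 3-class
# mixtures; TOP / non-TOP 5'UTR sequences; and Hill-curve dose surfaces with
# optional injected synergy.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' ~6% of genes translationally deregulated with downs outnumbering ups
#' roughly 3:1 (te up:down:stable = 0.015:0.047:0.938), effect magnitudes
#' |log2FC| uniform on \[0.7, 2.5\] (the observed log2 TI range is roughly
#' -2 to +2.5), base abundances lognormal(meanlog 6, sdlog 1) counts,
#' NB dispersions uniform on \[0.05, 0.2\] (variance mu + alpha*mu^2),
#' 3 replicates per group, and a polysome-loading factor rho = 0.8 whose
#' arbitrary scale cancels in the Translational Index. TOP motifs are
#' assigned with prevalence 0.25 among translationally up-regulated genes
#' versus 0.02 elsewhere.
#'
#' @param n_genes number of genes
#' @param replicates replicates per (fraction, condition) group
#' @param te_props,txn_props named 3-way proportions `c(up=, down=, stable=)`
#'   summing to 1
#' @param effect_range range of |log2 fold-change| for non-stable classes
#' @param base_meanlog,base_sdlog lognormal parameters of the expected
#'   cytoplasmic NT count
#' @param dispersion_range range of the NB dispersion alpha
#' @param libsize_range range of per-sample library-size factors
#' @param rho_poly polysome-loading factor (mean scale of polysomal vs
#'   cytoplasmic libraries); cancels in the TI
#' @param top_prev_te_up,top_prev_other probability a gene is a TOP gene,
#'   within the te-up class and elsewhere
#' @param seed mandatory RNG seed
#' @return list of class `SimConfig`
#' @export
sim_config <- function(n_genes = 5000, replicates = 3,
                       te_props = c(up = 0.015, down = 0.047, stable = 0.938),
                       txn_props = c(up = 0.05, down = 0.05, stable = 0.90),
                       effect_range = c(0.7, 2.5),
                       base_meanlog = 6, base_sdlog = 1,
                       dispersion_range = c(0.05, 0.2),
                       libsize_range = c(0.7, 1.3),
                       rho_poly = 0.8,
                       top_prev_te_up = 0.25, top_prev_other = 0.02,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  chk_props <- function(p, what) {
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " proportions must be 3 non-negative values summing to 1")
    if (is.null(names(p)) || !setequal(names(p), c("up", "down", "stable")))
      stop(what, " proportions must be named up/down/stable")
    p[c("up", "down", "stable")]
  }
  te_props <- chk_props(te_props, "te")
  txn_props <- chk_props(txn_props, "txn")
  stopifnot(n_genes >= 1, replicates >= 1,
            all(effect_range > 0), diff(effect_range) >= 0,
            all(dispersion_range > 0), all(libsize_range > 0),
            rho_poly > 0,
            top_prev_te_up >= 0, top_prev_te_up <= 1,
            top_prev_other >= 0, top_prev_other <= 1)
  structure(list(n_genes = n_genes, replicates = replicates,
                 te_props = te_props, txn_props = txn_props,
                 effect_range = effect_range,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 dispersion_range = dispersion_range,
                 libsize_range = libsize_range, rho_poly = rho_poly,
                 top_prev_te_up = top_prev_te_up,
                 top_prev_other = top_prev_other, seed = seed),
            class = "SimConfig")
}

#' Draw per-gene ground truth
#'
#' Assigns each gene a transcriptional and a translational-efficiency class
#' (multinomial around the configured proportions), signed log2 effect sizes
#' for the non-stable classes, a base abundance, an NB dispersion, and TOP
#' membership with the two configured prevalences.
#'
#' @param config [sim_config()] object
#' @return data.frame with columns `gene_id`, `txn_class`, `txn_log2fc`,
#'   `te_class`, `te_log2fc`, `base_mean`, `dispersion`, `is_top`
#' @export
simulate_gene_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, {
    n <- config$n_genes
    classes <- c("up", "down", "stable")
    draw_class <- function(p) sample(classes, n, replace = TRUE, prob = p)
    draw_fc <- function(cls) {
      mag <- stats::runif(n, config$effect_range[1], config$effect_range[2])
      ifelse(cls == "up", mag, ifelse(cls == "down", -mag, 0))
    }
    txn_class <- draw_class(config$txn_props)
    te_class <- draw_class(config$te_props)
    top_p <- ifelse(te_class == "up", config$top_prev_te_up,
                    config$top_prev_other)
    data.frame(
      gene_id = sprintf("g%04d", seq_len(n)),
      txn_class = txn_class,
      txn_log2fc = draw_fc(txn_class),
      te_class = te_class,
      te_log2fc = draw_fc(te_class),
      base_mean = stats::rlnorm(n, config$base_meanlog, config$base_sdlog),
      dispersion = stats::runif(n, config$dispersion_range[1],
                                config$dispersion_range[2]),
      is_top = stats::runif(n) < top_p,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate NB counts for the four polysome-profiling groups
#'
#' Counts are negative binomial with
#' `mu(g, s) = base_mean * sizefactor(s) * 2^(txn_log2fc * [T]) *
#' rho(fraction) * 2^(te_log2fc * [T & polysomal])` and per-gene dispersion
#' alpha (variance `mu + alpha mu^2`). `rho(polysomal)` is the configured
#' polysome-loading factor, `rho(cytoplasmic) = 1`; its scale cancels in the
#' Translational Index.
#'
#' @param truth data.frame from [simulate_gene_truth()]
#' @param config [sim_config()] object
#' @return [count_dataset()] with `4 * replicates` samples
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "SimConfig"), nrow(truth) >= 1)
  with_seed(config$seed + 1L, {
    reps <- config$replicates
    design <- expand.grid(replicate = seq_len(reps),
                          condition = c("NT", "T"),
                          fraction = c("cytoplasmic", "polysomal"),
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%s_r%d",
                                ifelse(design$fraction == "polysomal", "poly", "cyto"),
                                design$condition, design$replicate)
    sf <- stats::runif(nrow(design), config$libsize_range[1],
                       config$libsize_range[2])
    n <- nrow(truth)
    counts <- matrix(0, n, nrow(design),
                     dimnames = list(truth$gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      is_t <- design$condition[j] == "T"
      is_poly <- design$fraction[j] == "polysomal"
      mu <- truth$base_mean * sf[j] *
        2^(truth$txn_log2fc * is_t) *
        (if (is_poly) config$rho_poly else 1) *
        2^(truth$te_log2fc * (is_t && is_poly))
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / truth$dispersion)
    }
    count_dataset(counts, design[, c("sample_id", "fraction", "condition",
                                     "replicate")])
  })
}

#' Simulate 5'UTR sequences consistent with TOP ground truth
#'
#' TOP genes receive a 5'UTR starting with a cap-adjacent C followed by 4-15
#' further pyrimidines and then a G-rich stretch; non-TOP genes either start
#' with a purine or carry an initial pyrimidine run too short to qualify
#' (total run < 5). Lengths are 20-200 nt.
#'
#' @param truth data.frame with `gene_id` and `is_top`
#' @param seed RNG seed
#' @return data.frame with `gene_id`, `sequence` (alphabet ACGT, position 1
#'   = transcription start site)
#' @export
simulate_utrs <- function(truth, seed) {
  stopifnot(nrow(truth) >= 1)
  with_seed(seed, {
    rand_tail <- function(len) {
      if (len <= 0) return("")
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }
    one <- function(is_top) {
      len <- sample(20:200, 1)
      if (is_top) {
        run <- 1 + sample(4:15, 1)  # initial C plus 4-15 more pyrimidines
        g_len <- min(10, len - run)
        g_stretch <- paste(sample(c("G", "A"), g_len, replace = TRUE,
                                  prob = c(0.8, 0.2)), collapse = "")
        head <- paste0("C", paste(sample(c("C", "T"), run - 1, replace = TRUE),
                                  collapse = ""), g_stretch)
        paste0(head, rand_tail(len - nchar(head)))
      } else if (stats::runif(1) < 0.5) {
        paste0(sample(c("A", "G"), 1), rand_tail(len - 1))
      } else {
        # starts with C but the pyrimidine run stops short of the motif
        run <- sample(1:3, 1)
        head <- paste0("C", paste(rep("T", run - 1), collapse = ""), "A")
        paste0(head, rand_tail(len - nchar(head)))
      }
    }
    data.frame(gene_id = truth$gene_id,
               sequence = vapply(truth$is_top, one, character(1)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a dose-response surface with known synergy
#'
#' Monotherapy margins follow the two Hill curves exactly (plus optional
#' Gaussian noise); interior cells are the Loewe-additive expected effect
#' plus `synergy_offset` (plus noise). A negative offset deepens inhibition
#' below the additive expectation, i.e. injects synergy under the
#' "positive score = synergy" convention of [synergy_score()].
#'
#' @param hill_a,hill_b [hill_params()] of the two monotherapies
#' @param doses_a,doses_b ascending dose vectors starting at 0
#' @param synergy_offset additive shift of interior effects (fraction of
#'   control; negative = synergy)
#' @param noise_sd Gaussian noise sd added to every cell
#' @param seed RNG seed
#' @return `DoseMatrix`
#' @export
simulate_dose_surface <- function(hill_a, hill_b, doses_a, doses_b,
                                  synergy_offset = 0, noise_sd = 0, seed = 1) {
  stopifnot(doses_a[1] == 0, doses_b[1] == 0)
  with_seed(seed, {
    na <- length(doses_a); nb <- length(doses_b)
    resp <- matrix(NA_real_, na, nb)
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      e <- loewe_expected(doses_a[i], doses_b[j], hill_a, hill_b)
      if (doses_a[i] > 0 && doses_b[j] > 0) e <- e + synergy_offset
      resp[i, j] <- e
    }
    if (noise_sd > 0)
      resp <- resp + matrix(stats::rnorm(na * nb, 0, noise_sd), na, nb)
    dose_matrix(doses_a, doses_b, resp)
  })
}
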