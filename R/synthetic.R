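## Synthetic paired tumor/healthy study generator. The generative model for
## counts mirrors the inference model (log-link Dirichlet-multinomial with a
## sparse coefficient matrix), so parameter-recovery checks are well-posed.

#' Ground truth of a synthetic study
#'
#' @param coefficient_matrix (K+1) x J real matrix on the log-concentration
#'   scale; row 1 is the intercept (log baseline proportions), rows 2..K+1
#'   the covariate effects.
#' @param active_set Data frame with columns `covariate` (1..K) and
#'   `category` (1..J) listing the nonzero covariate effects. Every
#'   covariate-row entry outside this set must be exactly zero.
#' @param overdispersion Total Dirichlet concentration scale (> 0); the
#'   concentration of sample i is `overdispersion * exp(X_i B)`.
#' @param seed Integer seed recorded for provenance.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(coefficient_matrix, active_set, overdispersion,
                         seed = NA_integer_) {
  coefficient_matrix <- as.matrix(coefficient_matrix)
  if (!is.finite(overdispersion) || overdispersion <= 0) {
    stop("`overdispersion` must be a positive real")
  }
  k_cov <- nrow(coefficient_matrix) - 1
  j_dim <- ncol(coefficient_matrix)
  active_set <- as.data.frame(active_set)
  if (nrow(active_set) > 0) {
    stopifnot(all(active_set$covariate %in% seq_len(k_cov)),
              all(active_set$category %in% seq_len(j_dim)))
  }
  mask <- matrix(FALSE, k_cov, j_dim)
  if (nrow(active_set) > 0) {
    mask[cbind(active_set$covariate, active_set$category)] <- TRUE
  }
  cov_rows <- coefficient_matrix[-1, , drop = FALSE]
  if (any(cov_rows[!mask] != 0)) {
    stop("coefficients outside the active set must be exactly zero")
  }
  structure(list(coefficient_matrix = coefficient_matrix,
                 active_set = active_set,
                 overdispersion = overdispersion,
                 seed = seed),
            class = "ground_truth")
}

#' Generate a paired-design cytokine panel
#'
#' Draws per-cytokine log-normal concentrations for `n_patients` patients,
#' two samples each (tumor `<id>_T`, healthy `<id>_H`). The log-scale model
#' is `mu_c + patient effect + residual`, with the tumor sample additionally
#' shifted by `tissue_shift[c]`; the shared patient effect makes the paired
#' design informative. Default per-cytokine medians sit one log unit above
#' the LLOQ so that the censoring path is exercised by the lower tail.
#' Censoring itself is applied downstream by [apply_loq()], not here.
#'
#' @param n_patients Number of patients (>= 2); the panel has `2 *
#'   n_patients` rows.
#' @param cytokine_names Unique cytokine names, all present in `loq`.
#' @param tissue_shift Log-scale tumor-vs-healthy shift, scalar or one value
#'   per cytokine (default 0).
#' @param loq A [read_loq_table()] (default: the packaged 26-cytokine
#'   panel), used to anchor the log-normal medians.
#' @param seed Integer seed.
#' @param sdlog Within-patient log-scale residual sd (default 1.0).
#' @param patient_sd Log-scale patient-effect sd (default 0.5).
#' @return A [cytokine_panel()] of uncensored concentrations (pg/ml).
#' @export
generate_cytokine_panel <- function(n_patients, cytokine_names,
                                    tissue_shift = 0,
                                    loq = read_loq_table(), seed,
                                    sdlog = 1.0, patient_sd = 0.5) {
  if (n_patients < 2 || n_patients != round(n_patients)) {
    stop("`n_patients` must be an integer >= 2")
  }
  if (anyDuplicated(cytokine_names)) stop("duplicate cytokine names")
  k <- length(cytokine_names)
  if (length(tissue_shift) == 1) tissue_shift <- rep(tissue_shift, k)
  if (length(tissue_shift) != k) {
    stop("`tissue_shift` must be scalar or one value per cytokine")
  }
  missing_cy <- setdiff(cytokine_names, loq$cytokine)
  if (length(missing_cy) > 0) {
    stop("cytokine(s) not in the LOQ table: ",
         paste(missing_cy, collapse = ", "))
  }
  mu <- log(loq$lloq[match(cytokine_names, loq$cytokine)]) + 1

  set.seed(seed)
  patients <- sprintf("P%03d", seq_len(n_patients))
  u <- matrix(stats::rnorm(n_patients * k, sd = patient_sd), n_patients, k)
  log_t <- sweep(u, 2, mu + tissue_shift, `+`) +
    matrix(stats::rnorm(n_patients * k, sd = sdlog), n_patients, k)
  log_h <- sweep(u, 2, mu, `+`) +
    matrix(stats::rnorm(n_patients * k, sd = sdlog), n_patients, k)
  vals <- exp(rbind(log_t, log_h))
  rownames(vals) <- c(paste0(patients, "_T"), paste0(patients, "_H"))
  colnames(vals) <- cytokine_names
  ## interleave tumor/healthy per patient for readability
  ord <- as.vector(rbind(paste0(patients, "_T"), paste0(patients, "_H")))
  cytokine_panel(vals[ord, , drop = FALSE])
}

#' Generate Dirichlet-multinomial counts from a design and ground truth
#'
#' For sample i the concentration vector is
#' `alpha_i = overdispersion * exp(X_i B)`; proportions are drawn from
#' `Dirichlet(alpha_i)` (via normalized gammas) and counts multinomially at
#' the prescribed depth, so each row sums to `depths[i]` exactly.
#'
#' @param design n x (K+1) real matrix, intercept column first.
#' @param truth A [ground_truth()] whose coefficient matrix has K+1 rows.
#' @param depths Positive integer vector of sequencing depths, length n.
#' @param seed Integer seed.
#' @param category_names Optional J category names.
#' @return A [composition_response()] with n rows.
#' @export
generate_dm_counts <- function(design, truth, depths, seed,
                               category_names = NULL) {
  design <- as.matrix(design)
  b_mat <- truth$coefficient_matrix
  if (ncol(design) != nrow(b_mat)) {
    stop("design has ", ncol(design), " columns but the coefficient matrix ",
         "has ", nrow(b_mat), " rows")
  }
  n <- nrow(design)
  if (length(depths) != n) stop("`depths` length must match design rows")
  if (any(depths < 1 | depths != round(depths))) {
    stop("`depths` must be positive integers")
  }
  alpha <- truth$overdispersion * exp(design %*% b_mat)
  if (any(!is.finite(alpha))) stop("non-finite concentration parameter")
  j_dim <- ncol(alpha)
  set.seed(seed)
  counts <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(j_dim, shape = alpha[i, ], rate = 1)
    while (sum(g) == 0) g <- stats::rgamma(j_dim, shape = alpha[i, ], rate = 1)
    as.numeric(stats::rmultinom(1, size = depths[i], prob = g / sum(g)))
  }, numeric(j_dim)))
  if (is.null(category_names)) {
    category_names <- colnames(b_mat)
    if (is.null(category_names)) {
      category_names <- c(paste0("category_", seq_len(j_dim - 1)), "residual")
    }
  }
  colnames(counts) <- category_names
  rownames(counts) <- rownames(design)
  composition_response(counts)
}

#' Default configuration of a synthetic paired study
#'
#' The defaults are the study conditions the rest of the package is tested
#' under: 40 patients with one tumor and one healthy sample each, a
#' 4-category response (three dominant genera plus the residual), 8
#' cytokine covariates with log-normal marginals anchored to the packaged
#' LOQ panel, sequencing depths uniform on `[1e4, 1e5]`, total Dirichlet
#' concentration 50, and a sparse coefficient matrix with 2 active
#' covariate-category effects of magnitude 1.5.
#'
#' @param n_patients Number of patients.
#' @param n_cytokines Number of cytokine covariates K (names taken from the
#'   packaged panel unless `cytokine_names` is given).
#' @param n_categories Response categories J (>= 2), last is the residual.
#' @param n_active Number of nonzero covariate-category effects.
#' @param effect_size Magnitude of each active coefficient (random sign).
#' @param depth_range Sequencing-depth range (uniform integer draw).
#' @param overdispersion Total Dirichlet concentration.
#' @param tissue_shift Log-scale tumor shift of the cytokines (scalar or
#'   length K).
#' @param baseline_proportions Length-J positive vector summing to 1; its
#'   log is the intercept row. Default mimics a gut mucosa profile dominated
#'   by Bacteroides and Prevotella.
#' @param top_genus_names The J-1 named genera of the response.
#' @param cytokine_names Optional explicit cytokine names.
#' @param transform Covariate transform used to build the design the counts
#'   are generated from (see [standardize_covariates()]).
#' @param n_residual_genera Number of background genera the residual
#'   category is split into when building the OTU table.
#' @param seed Integer seed.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_patients = 40, n_cytokines = 8, n_categories = 4,
                         n_active = 2, effect_size = 1.5,
                         depth_range = c(1e4, 1e5), overdispersion = 50,
                         tissue_shift = 0,
                         baseline_proportions = NULL,
                         top_genus_names = c("Bacteroides", "Prevotella",
                                             "Escherichia/Shigella"),
                         cytokine_names = NULL,
                         transform = "log1p_zscore",
                         n_residual_genera = 20,
                         seed = 1) {
  if (n_categories < 2) stop("need J >= 2 response categories")
  if (n_cytokines < 1) stop("need K >= 1 cytokines")
  if (n_active > n_cytokines * n_categories) {
    stop("more active pairs than covariate-category cells")
  }
  if (is.null(cytokine_names)) {
    panel_names <- read_loq_table()$cytokine
    if (n_cytokines > length(panel_names)) {
      stop("at most ", length(panel_names), " packaged cytokine names")
    }
    cytokine_names <- panel_names[seq_len(n_cytokines)]
  }
  if (is.null(baseline_proportions)) {
    base <- c(0.35, 0.20, 0.10)
    if (n_categories == 4) {
      baseline_proportions <- c(base, 0.35)
    } else {
      p <- rev(seq_len(n_categories))
      baseline_proportions <- p / sum(p)
    }
  }
  stopifnot(length(baseline_proportions) == n_categories,
            all(baseline_proportions > 0),
            abs(sum(baseline_proportions) - 1) < 1e-8,
            length(top_genus_names) >= n_categories - 1)
  structure(list(n_patients = n_patients, n_cytokines = n_cytokines,
                 n_categories = n_categories, n_active = n_active,
                 effect_size = effect_size, depth_range = depth_range,
                 overdispersion = overdispersion, tissue_shift = tissue_shift,
                 baseline_proportions = baseline_proportions,
                 top_genus_names = top_genus_names[seq_len(n_categories - 1)],
                 cytokine_names = cytokine_names, transform = transform,
                 n_residual_genera = n_residual_genera, seed = seed),
            class = "study_config")
}

.derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7 + offset * 1000003) %% 2147483647)
}

#' Generate a complete synthetic paired study
#'
#' Assembles a mutually consistent cytokine panel, composition response,
#' OTU table, pairing table and recorded ground truth under one seed. The
#' composition is drawn from the log-link Dirichlet-multinomial model using
#' the standardized, LLOQ-censored cytokines as design — the same design
#' the downstream analysis reconstructs — so coefficient recovery is
#' well-posed. The OTU table realizes each response category as taxa: the
#' named genera keep their counts (split over a few OTUs each) and the
#' residual category is spread multinomially over background genera, so
#' genus aggregation followed by [build_composition_response()] returns the
#' generated composition exactly.
#'
#' @param config A [study_config()].
#' @return Object of class `synthetic_study`: list with `cytokine_panel`
#'   (uncensored), `cytokine_panel_censored`, `design`, `composition`,
#'   `otu_table`, `pairing`, `truth`, `config`.
#' @export
generate_paired_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  k <- config$n_cytokines
  j <- config$n_categories
  loq <- read_loq_table()

  panel <- generate_cytokine_panel(
    config$n_patients, config$cytokine_names,
    tissue_shift = config$tissue_shift, loq = loq,
    seed = .derive_seed(config$seed, 1)
  )
  censored <- apply_loq(panel, loq, uloq_policy = "clip")
  design <- standardize_covariates(censored, transform = config$transform)

  ## sparse truth: active cells sampled uniformly, signs random
  set.seed(.derive_seed(config$seed, 2))
  cells <- sample(k * j, config$n_active)
  active <- data.frame(covariate = (cells - 1) %% k + 1,
                       category = (cells - 1) %/% k + 1)
  b_mat <- matrix(0, k + 1, j)
  b_mat[1, ] <- log(config$baseline_proportions)
  signs <- sample(c(-1, 1), config$n_active, replace = TRUE)
  if (config$n_active > 0) {
    b_mat[cbind(active$covariate + 1, active$category)] <-
      signs * config$effect_size
  }
  colnames(b_mat) <- c(config$top_genus_names, "residual")
  rownames(b_mat) <- c("(Intercept)", config$cytokine_names)
  truth <- ground_truth(b_mat, active, config$overdispersion,
                        seed = config$seed)

  n_samples <- 2 * config$n_patients
  depths <- floor(stats::runif(n_samples, config$depth_range[1],
                               config$depth_range[2] + 1))
  composition <- generate_dm_counts(design$X, truth, depths,
                                    seed = .derive_seed(config$seed, 3))

  otu <- .composition_to_otu_table(composition, config,
                                   seed = .derive_seed(config$seed, 4))

  patients <- sprintf("P%03d", seq_len(config$n_patients))
  pairing <- sample_pairing(patients, paste0(patients, "_T"),
                            paste0(patients, "_H"))

  structure(list(cytokine_panel = panel, cytokine_panel_censored = censored,
                 design = design, composition = composition, otu_table = otu,
                 pairing = pairing, truth = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", x$config$n_patients, "patients (paired),",
      x$config$n_cytokines, "cytokines,", x$config$n_categories,
      "response categories,", nrow(x$truth$active_set),
      "active effects, seed", x$config$seed, "\n")
  invisible(x)
}

## Expand a category-level composition into an OTU table whose genus
## aggregation reproduces it: named genera get 2 OTUs each (80/20 split),
## the residual is spread over background genera (1 OTU each) with
## geometric-ish weights so rare taxa, singletons included, occur.
.composition_to_otu_table <- function(composition, config, seed) {
  set.seed(seed)
  counts <- composition$counts
  n <- nrow(counts)
  j <- ncol(counts)
  n_bg <- config$n_residual_genera
  bg_names <- sprintf("ResidualGenus%02d", seq_len(n_bg))
  ## flat-ish decreasing weights, largest well below the rarest named
  ## category's baseline share so the named genera stay the top-k by total
  bg_w <- 1 / (seq_len(n_bg) + 5)
  bg_w <- bg_w / sum(bg_w)

  blocks <- list()
  tax <- list()
  phyla <- c("Bacteroidetes", "Bacteroidetes", "Proteobacteria")
  for (g in seq_len(j - 1)) {
    otus <- paste0("OTU_", gsub("[^A-Za-z]", "", composition$category_names[g]),
                   "_", 1:2)
    split <- t(vapply(counts[, g], function(m) {
      as.numeric(stats::rmultinom(1, m, prob = c(0.8, 0.2)))
    }, numeric(2)))
    colnames(split) <- otus
    blocks[[g]] <- split
    ph <- if (g <= length(phyla)) phyla[g] else "Firmicutes"
    tax[[g]] <- data.frame(taxon_id = otus, phylum = ph,
                           class = "unclassified", order = "unclassified",
                           family = "unclassified",
                           genus = composition$category_names[g],
                           stringsAsFactors = FALSE)
  }
  resid_split <- t(vapply(counts[, j], function(m) {
    as.numeric(stats::rmultinom(1, m, prob = bg_w))
  }, numeric(n_bg)))
  colnames(resid_split) <- paste0("OTU_", bg_names)
  blocks[[j]] <- resid_split
  bg_phyla <- rep(c("Firmicutes", "Proteobacteria", "Actinobacteria",
                    "Fusobacteria", "Verrucomicrobia"), length.out = n_bg)
  tax[[j]] <- data.frame(taxon_id = paste0("OTU_", bg_names),
                         phylum = bg_phyla, class = "unclassified",
                         order = "unclassified", family = "unclassified",
                         genus = bg_names, stringsAsFactors = FALSE)
  m <- do.call(cbind, blocks)
  rownames(m) <- rownames(counts)
  otu_table(m, do.call(rbind, tax))
}

#' Write every table of a synthetic study to disk
#'
#' Emits counts TSV, taxonomy TSV, cytokines CSV (uncensored), pairing TSV
#' and a ground-truth JSON into `dir`.
#'
#' @param study A [generate_paired_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             cytokines = file.path(dir, "cytokines.csv"),
             pairing = file.path(dir, "pairing.tsv"),
             truth = file.path(dir, "truth.json"))
  write_otu_table(study$otu_table, paths["counts"], paths["taxonomy"])
  write_cytokine_panel(study$cytokine_panel, paths["cytokines"])
  write_sample_pairing(study$pairing, paths["pairing"])
  truth <- study$truth
  jsonlite::write_json(
    list(coefficient_matrix = truth$coefficient_matrix,
         active_set = truth$active_set,
         overdispersion = truth$overdispersion,
         seed = truth$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
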