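#' Simulation configuration
#'
#' Parameters of the synthetic paired-cohort generator. Defaults emulate the
#' study conditions the pipeline is designed for: a cohort of 38 coronary
#' artery disease patients with paired baseline/LPS-stimulated monocyte
#' profiles, co-expressed response modules of at least 50 genes, one module
#' whose per-patient response tracks diastolic blood pressure (DBP), and
#' planted TF regulons with signed modes of regulation.
#'
#' @param n_genes Total number of genes (default 2000).
#' @param n_patients Number of patients with paired samples (default 38).
#' @param n_modules Number of planted co-expression modules (default 6).
#' @param module_sizes Integer vector of module sizes, each >= 50; defaults to
#'   100 genes per module.
#' @param within_module_cor Target pairwise response correlation between genes
#'   of one module, in (0,1) (default 0.7).
#' @param trait_effect Correlation between the trait-linked module's latent
#'   response factor and DBP, in (-1,1) (default 0.6).
#' @param n_tfs Number of planted transcription factors (default 40).
#' @param targets_per_tf Targets per TF regulon (default 25).
#' @param repressor_fraction Fraction of TFs acting as repressors
#'   (all-negative mode of regulation; default 0.3).
#' @param noise_sd Per-gene response noise standard deviation on the log2
#'   scale (default 0.5).
#' @param seed Integer RNG seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000, n_patients = 38, n_modules = 6,
                              module_sizes = rep(100L, n_modules),
                              within_module_cor = 0.7, trait_effect = 0.6,
                              n_tfs = 40, targets_per_tf = 25,
                              repressor_fraction = 0.3, noise_sd = 0.5,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              within_module_cor = within_module_cor, trait_effect = trait_effect,
              n_tfs = as.integer(n_tfs), targets_per_tf = as.integer(targets_per_tf),
              repressor_fraction = repressor_fraction, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("module_sizes must have length n_modules", call. = FALSE)
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("sum of module sizes exceeds n_genes", call. = FALSE)
  if (abs(cfg$trait_effect) >= 1) stop("|trait_effect| must be < 1", call. = FALSE)
  if (cfg$within_module_cor < 0 || cfg$within_module_cor >= 1)
    stop("within_module_cor must be in [0,1)", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (any(c(cfg$n_genes, cfg$n_patients, cfg$n_tfs, cfg$targets_per_tf) < 1))
    stop("counts must be positive", call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

# Table-1 cohort moments used to generate realistic clinical covariates.
.COHORT_MOMENTS <- list(
  age = c(66.68, 8.65), bmi = c(27.13, 4.14), heart_rate = c(63.29, 10.32),
  dbp = c(74.78, 11.88), glucose = c(6.41, 1.15), triglyceride = c(1.55, 0.8),
  creatinine = c(87.45, 21.3), hdl = c(1.11, 0.3), ldl = c(2.64, 0.91))
.COHORT_BINARY_P <- c(sex = 20 / 38, renal_failure = 3 / 38,
                      smoker = 7 / 38, diabetes = 7 / 38)

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.simulate_clinical <- function(n_patients, patient_ids) {
  clin <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
  for (col in names(.COHORT_BINARY_P))
    clin[[col]] <- stats::rbinom(n_patients, 1L, .COHORT_BINARY_P[[col]])
  m <- .COHORT_MOMENTS
  clin$age <- .rtrunc_norm(n_patients, m$age[1], m$age[2], 30, 100)
  clin$bmi <- .rtrunc_norm(n_patients, m$bmi[1], m$bmi[2], 15, 50)
  clin$heart_rate <- .rtrunc_norm(n_patients, m$heart_rate[1], m$heart_rate[2], 35, 130)
  clin$dbp <- .rtrunc_norm(n_patients, m$dbp[1], m$dbp[2], 40, 130)
  # SBP = DBP plus a positive pulse pressure, giving the expected DBP-SBP correlation
  pulse_sd <- sqrt(max(21.35^2 - m$dbp[2]^2, 8^2))
  clin$sbp <- clin$dbp + .rtrunc_norm(n_patients, 137.68 - m$dbp[1], pulse_sd, 10, Inf)
  clin$glucose <- .rtrunc_norm(n_patients, m$glucose[1], m$glucose[2], 2, Inf)
  clin$triglyceride <- .rtrunc_norm(n_patients, m$triglyceride[1], m$triglyceride[2], 0.2, Inf)
  clin$creatinine <- .rtrunc_norm(n_patients, m$creatinine[1], m$creatinine[2], 20, Inf)
  clin$hdl <- .rtrunc_norm(n_patients, m$hdl[1], m$hdl[2], 0.3, Inf)
  clin$ldl <- .rtrunc_norm(n_patients, m$ldl[1], m$ldl[2], 0.3, Inf)
  class(clin) <- c("ClinicalTable", "data.frame")
  clin
}

#' Simulate a paired baseline/stimulated cohort with planted structure
#'
#' Generates a clinical table with Table-1-like covariate moments, baseline
#' log2 intensities around gene-specific means in the 6-14 range, and a
#' stimulated matrix equal to baseline plus a planted per-gene response.
#' Module genes share a patient-level latent response factor that yields the
#' configured within-module correlation; the first module's factor correlates
#' with DBP at `trait_effect`, and its genes are planted as downregulated
#' responders (the dampening phenotype the pipeline is built to detect).
#' TF target responses equal the mode-of-regulation sign times the TF's latent
#' activity plus noise. TFs and their targets are drawn from the gene pool
#' outside the modules; remaining pool genes are unassigned noise.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `baseline` and `stimulated`
#'   (`ExpressionMatrix`), `clinical` (`ClinicalTable`) and `truth`
#'   (planted `module_labels`, `regulons`, `tf_activity`, `mean_response`,
#'   `dag_edges`, `trait_module`, `tf_ids`).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes; np <- cfg$n_patients
  genes <- sprintf("G%04d", seq_len(ng))
  patients <- sprintf("P%02d", seq_len(np))
  clin <- .simulate_clinical(np, patients)

  # module membership: first sum(module_sizes) genes, in blocks
  labels <- rep("unassigned", ng)
  idx <- 1L
  for (m in seq_len(cfg$n_modules)) {
    labels[idx:(idx + cfg$module_sizes[m] - 1L)] <- sprintf("M%d", m)
    idx <- idx + cfg$module_sizes[m]
  }
  names(labels) <- genes

  # latent per-patient module factors; M1 is tied to DBP at trait_effect
  z_dbp <- as.numeric(scale(clin$dbp))
  factors <- matrix(stats::rnorm(cfg$n_modules * np), cfg$n_modules, np)
  factors[1, ] <- cfg$trait_effect * z_dbp +
    sqrt(1 - cfg$trait_effect^2) * stats::rnorm(np)

  w <- cfg$within_module_cor
  loading <- if (w > 0) cfg$noise_sd * sqrt(w / (1 - w)) else 0

  # planted per-gene mean responses: trait module downregulated, others mixed
  mu <- stats::rnorm(ng, 0, 0.3)
  mod_idx <- which(labels != "unassigned")
  mu[mod_idx] <- stats::rnorm(length(mod_idx), 0, 1.2)
  m1_idx <- which(labels == "M1")
  mu[m1_idx] <- -abs(stats::rnorm(length(m1_idx), 1.5, 0.5))

  response <- matrix(stats::rnorm(ng * np, 0, cfg$noise_sd), ng, np,
                     dimnames = list(genes, patients))
  for (m in seq_len(cfg$n_modules)) {
    gi <- which(labels == sprintf("M%d", m))
    response[gi, ] <- response[gi, ] +
      loading * matrix(factors[m, ], length(gi), np, byrow = TRUE)
  }

  # TF regulons in the unassigned pool
  pool <- which(labels == "unassigned")
  need <- cfg$n_tfs * (1L + cfg$targets_per_tf)
  if (length(pool) < need)
    stop("gene pool too small for the requested regulons", call. = FALSE)
  picked <- sample(pool, need)
  tf_idx <- picked[seq_len(cfg$n_tfs)]
  target_idx <- matrix(picked[-seq_len(cfg$n_tfs)], nrow = cfg$n_tfs)
  tf_ids <- genes[tf_idx]
  is_repressor <- seq_len(cfg$n_tfs) <= round(cfg$repressor_fraction * cfg$n_tfs)
  activity <- matrix(stats::rnorm(cfg$n_tfs * np), cfg$n_tfs, np,
                     dimnames = list(tf_ids, patients))
  regulons <- vector("list", cfg$n_tfs)
  names(regulons) <- tf_ids
  for (t in seq_len(cfg$n_tfs)) {
    # the TF's own response closely tracks its activity
    response[tf_idx[t], ] <- activity[t, ] + stats::rnorm(np, 0, 0.25)
    mu[tf_idx[t]] <- 0
    tg <- target_idx[t, ]
    mor <- rep(if (is_repressor[t]) -1 else 1, cfg$targets_per_tf)
    response[tg, ] <- mor %o% activity[t, ] +
      matrix(stats::rnorm(length(tg) * np, 0, cfg$noise_sd),
             length(tg), np)
    regulons[[t]] <- data.frame(target = genes[tg], mor = mor, weight = 1,
                                stringsAsFactors = FALSE)
  }

  response <- response + mu  # recycles down columns: per-gene mean shift

  base_mean <- stats::runif(ng, 6, 14)
  baseline_vals <- base_mean +
    matrix(stats::rnorm(ng * np, 0, 0.4), ng, np)
  dimnames(baseline_vals) <- list(genes, patients)
  stimulated_vals <- baseline_vals + response

  mk_expr <- function(vals, cond) {
    sid <- paste0(patients, "_", cond)
    colnames(vals) <- sid
    expression_matrix(vals,
                      condition = stats::setNames(rep(cond, np), sid),
                      patient_id = stats::setNames(patients, sid))
  }

  truth <- list(module_labels = labels,
                regulons = regulons,
                tf_activity = activity,
                tf_ids = tf_ids,
                mean_response = stats::setNames(mu, genes),
                module_factors = factors,
                dag_edges = data.frame(from = "M1", to = "dbp",
                                       stringsAsFactors = FALSE),
                trait_module = "M1")
  list(baseline = mk_expr(baseline_vals, "baseline"),
       stimulated = mk_expr(stimulated_vals, "stimulated"),
       clinical = clin, truth = truth)
}

#' Simulate a drug-signature library
#'
#' Builds a drug-by-gene differential-score matrix over a landmark gene panel
#' containing all trait-module genes. The planted `mimic` drug's signature is
#' the planted mean LPS response itself; the `reversal` drug is its exact
#' negative (their correlation is -1 by construction); all other drugs are
#' standard-normal noise. Each drug carries a cell-line label so screens can
#' be restricted to a relevant subset (as one would restrict a public
#' signature library to myeloid lines).
#'
#' @param cfg The [simulation_config()] used for the cohort.
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @param n_drugs Number of drugs (default 50).
#' @param n_landmark Size of the landmark gene panel (default 978, the size
#'   of a typical public landmark-gene panel).
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return List of class `DrugSignatureLibrary`: `scores` (drugs x genes),
#'   `cell_line` (named character), `mimic_drug`, `reversal_drug`.
#' @export
simulate_drug_library <- function(cfg, truth, n_drugs = 50, n_landmark = 978,
                                  seed = cfg$seed + 1L) {
  genes <- names(truth$module_labels)
  if (n_landmark > length(genes))
    stop("n_landmark exceeds the number of genes", call. = FALSE)
  set.seed(seed)
  mod_genes <- names(truth$module_labels)[truth$module_labels == truth$trait_module]
  if (length(mod_genes) == 0) stop("truth has no trait-module genes", call. = FALSE)
  extra <- setdiff(genes, mod_genes)
  landmark <- c(mod_genes, sample(extra, max(0, n_landmark - length(mod_genes))))
  landmark <- landmark[seq_len(min(n_landmark, length(landmark)))]

  drugs <- sprintf("DRUG%03d", seq_len(n_drugs))
  scores <- matrix(stats::rnorm(n_drugs * length(landmark)), n_drugs,
                   length(landmark), dimnames = list(drugs, landmark))
  mimic <- drugs[1]; reversal <- drugs[2]
  planted <- truth$mean_response[landmark]
  scores[mimic, ] <- planted
  scores[reversal, ] <- -planted

  myeloid <- c("HL60", "THP1", "NOMO1", "SKM1", "PL21", "U266", "HS27A")
  cell_line <- stats::setNames(
    rep_len(c(myeloid, "HEPG2", "MCF7"), n_drugs), drugs)
  cell_line[c(mimic, reversal)] <- "THP1"

  structure(list(scores = scores, cell_line = cell_line,
                 mimic_drug = mimic, reversal_drug = reversal),
            class = "DrugSignatureLibrary")
}

#' Write a drug-signature library as TSV
#'
#' Layout: first column `drug_id`, second `cell_line`, remaining columns one
#' per landmark gene.
#'
#' @param lib A `DrugSignatureLibrary` (or compatible list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_library <- function(lib, path) {
  df <- data.frame(drug_id = rownames(lib$scores),
                   cell_line = unname(lib$cell_line[rownames(lib$scores)]),
                   lib$scores, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a drug-signature library TSV written by [write_drug_library()]
#'
#' @param path Path to the TSV.
#' @return A `DrugSignatureLibrary` (without planted drug annotations).
#' @export
read_drug_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  scores <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(scores) <- df$drug_id
  structure(list(scores = scores,
                 cell_line = stats::setNames(df$cell_line, df$drug_id),
                 mimic_drug = NA_character_, reversal_drug = NA_character_),
            class = "DrugSignatureLibrary")
}
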