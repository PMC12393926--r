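# Synthetic trial generator with embedded ground truth. Every generator is
# the exact inverse of its analysis stage when its noise is zero, so the
# whole pipeline is testable without external data.

# Deterministic substream seed from a shared integer seed and a stream key,
# so generation order never affects reproducibility.
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Mean-one multiplicative lognormal noise (returns 1 when cv = 0).
lognorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Ground-truth configuration for a synthetic trial
#'
#' Defaults are the emulated study conditions: 3 diets x 3 replicate
#' tanks x 90 fish, a 65-day growth period at a constant 23.5 degC, true
#' ADCs, FCRs, growth (as TGC fitted to the reference final weights),
#' body-composition endpoints and expression fold-changes taken from the
#' bundled reference tables.
#'
#' Noise scales: `adc_noise_cv` acts multiplicatively on the indigestible
#' fraction (100 - ADC), which keeps recovered tank ADCs exactly unbiased;
#' `fcr_noise_cv` on the true FCR; `growth_noise_cv` on the final mean
#' weight; `composition_noise_cv` on final body-composition fields;
#' `ct_noise_sd` is additive on the Ct scale (cycles). Setting every noise
#' parameter to zero (and `survival_range = c(1, 1)`) makes the generator
#' the exact inverse of the analysis stages.
#'
#' @param diets Named list of [diet_spec()]s (default [reference_diets()]).
#' @param true_adc Named list (by diet) of named vectors with entries
#'   `dm`, `protein`, `lipid`, `phosphorus`, `energy` (%).
#' @param true_fcr,true_fbw,true_vsi,true_hsi,true_k Named numeric vectors
#'   by diet.
#' @param ibw Initial mean body weight, g.
#' @param n_replicates,n_fish,days Design constants.
#' @param temperature Daily temperature series (scalar recycled), degC.
#' @param body_comp_initial A [body_composition()] for the initial pool.
#' @param body_comp_final Named list (by diet) of [body_composition()]s.
#' @param expression_design Tibble with `gene`, `diet`, `fold_growth`
#'   (designed expression relative to the CTRL growth-period group) and
#'   `fold_post` (designed challenge/growth ratio within the diet).
#' @param genes Tibble with `gene`, `efficiency` (%), `role`.
#' @param samples_per_tank qPCR samples (fish) per tank and period.
#' @param ct_noise_sd Ct noise SD, cycles.
#' @param adc_noise_cv,fcr_noise_cv,growth_noise_cv,composition_noise_cv
#'   Multiplicative noise CVs (fractions).
#' @param fish_weight_cv Within-tank individual size variation (fraction).
#' @param survival_range Per-tank survival probability range for the
#'   binomial mortality draw.
#' @param n_sampled_fish Fish sampled per tank for morphometry.
#' @param seed Shared integer seed driving all substreams.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(diets = reference_diets(),
                         true_adc = NULL, true_fcr = NULL, true_fbw = NULL,
                         true_vsi = NULL, true_hsi = NULL, true_k = NULL,
                         ibw = 14.1, n_replicates = 3, n_fish = 90,
                         days = 65, temperature = 23.5,
                         body_comp_initial = NULL, body_comp_final = NULL,
                         expression_design = NULL, genes = NULL,
                         samples_per_tank = 3, ct_noise_sd = 0.3,
                         adc_noise_cv = 0.10, fcr_noise_cv = 0.04,
                         growth_noise_cv = 0.03,
                         composition_noise_cv = 0.02,
                         fish_weight_cv = 0.12,
                         survival_range = c(0.93, 0.97),
                         n_sampled_fish = 12, seed = 1L) {
  ref <- reference_tables()
  diet_names <- names(diets)
  pick <- function(tb, ind) {
    stats::setNames(tb$mean[match(paste(diet_names, ind),
                                  paste(tb$diet, tb$indicator))],
                    diet_names)
  }
  if (is.null(true_adc)) {
    true_adc <- lapply(diet_names, function(d) {
      a <- ref$adc[ref$adc$diet == d, ]
      stats::setNames(a$mean, a$constituent)
    })
    names(true_adc) <- diet_names
  }
  if (is.null(true_fbw)) true_fbw <- pick(ref$performance, "fbw_g")
  if (is.null(true_fcr)) {
    fi <- pick(ref$performance, "fi_g_per_fish")
    true_fcr <- fi / (true_fbw - ibw)
  }
  if (is.null(true_vsi)) true_vsi <- pick(ref$performance, "vsi_pct")
  if (is.null(true_hsi)) true_hsi <- pick(ref$performance, "hsi_pct")
  if (is.null(true_k)) true_k <- pick(ref$performance, "k")
  bc_row <- function(pool) {
    b <- ref$body_composition[ref$body_composition$pool == pool, ]
    body_composition("wet", dm = b$dm, protein = b$protein,
                     lipid = b$lipid, ash = b$ash,
                     phosphorus = b$phosphorus, energy = b$energy)
  }
  if (is.null(body_comp_initial)) body_comp_initial <- bc_row("initial")
  if (is.null(body_comp_final)) {
    body_comp_final <- lapply(diet_names, bc_row)
    names(body_comp_final) <- diet_names
  }
  if (is.null(genes)) genes <- ref$genes[, c("gene", "efficiency", "role")]
  if (is.null(expression_design)) {
    tgt <- genes$gene[genes$role == "target"]
    down <- c("cat", "gpx", "il1b", "igm", "cox2", "cldn12", "tjp2", "ocl")
    expression_design <- tidyr::expand_grid(gene = tgt, diet = diet_names)
    ex <- ref$expression
    expression_design$fold_growth <- ifelse(
      expression_design$diet == "CTRL", 1,
      ex$mean[match(paste(expression_design$gene, expression_design$diet),
                    paste(ex$gene, ex$diet))])
    expression_design$fold_growth[is.na(expression_design$fold_growth)] <- 1
    expression_design$fold_post <-
      ifelse(expression_design$gene %in% down, 0.5, 1)
  }
  if (any(expression_design$fold_growth <= 0) ||
      any(expression_design$fold_post <= 0)) {
    stop("designed fold-changes must be positive", call. = FALSE)
  }
  if (length(temperature) == 1L) temperature <- rep(temperature, days)
  if (n_replicates < 1) stop("need at least one replicate tank",
                             call. = FALSE)
  for (ad in true_adc) {
    if (any(ad <= 0 | ad >= 100)) {
      stop("true ADCs must lie strictly inside (0, 100)%", call. = FALSE)
    }
  }
  true_tgc <- vapply(diet_names, function(d) {
    fit_tgc(ibw, true_fbw[[d]], temperature)
  }, numeric(1))
  structure(
    list(diets = diets, true_adc = true_adc, true_fcr = true_fcr,
         true_fbw = true_fbw, true_tgc = true_tgc, true_vsi = true_vsi,
         true_hsi = true_hsi, true_k = true_k, ibw = ibw,
         n_replicates = n_replicates, n_fish = n_fish, days = days,
         temperature = temperature, body_comp_initial = body_comp_initial,
         body_comp_final = body_comp_final,
         expression_design = tibble::as_tibble(expression_design),
         genes = tibble::as_tibble(genes),
         samples_per_tank = samples_per_tank, ct_noise_sd = ct_noise_sd,
         adc_noise_cv = adc_noise_cv, fcr_noise_cv = fcr_noise_cv,
         growth_noise_cv = growth_noise_cv,
         composition_noise_cv = composition_noise_cv,
         fish_weight_cv = fish_weight_cv, survival_range = survival_range,
         n_sampled_fish = n_sampled_fish, seed = as.integer(seed)),
    class = "truth_config")
}

#' Zero every noise source of a truth configuration
#'
#' Convenience for round-trip tests: returns the configuration with all
#' noise CVs/SDs at zero and survival fixed at 1, under which every
#' analysis stage recovers the configured truth exactly.
#'
#' @param cfg A [truth_config()].
#' @return The modified configuration.
#' @export
noiseless <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  cfg$ct_noise_sd <- 0
  cfg$adc_noise_cv <- 0
  cfg$fcr_noise_cv <- 0
  cfg$growth_noise_cv <- 0
  cfg$composition_noise_cv <- 0
  cfg$fish_weight_cv <- 0
  cfg$survival_range <- c(1, 1)
  cfg
}

#' Simulate faecal samples consistent with designed true ADCs
#'
#' Inverts the marker-ratio formulas so that with zero noise the
#' digestibility stage recovers the designed ADCs exactly:
#' faecal marker = diet marker (DM) / (1 - ADC_dm/100); faecal constituent
#' = diet level (DM) x (1 - ADC/100) / (1 - ADC_dm/100). Tank noise is
#' multiplicative mean-one lognormal on each indigestible fraction
#' (100 - ADC), i.e. on tank-to-tank digestibility itself, which leaves
#' recovered tank ADCs exactly unbiased.
#'
#' @param diet A [diet_spec()].
#' @param true_adcs Named vector with `dm`, `protein`, `lipid`,
#'   `phosphorus`, `energy` (%), each strictly below 100.
#' @param noise_cv CV of the indigestibility noise (fraction).
#' @param seed Integer seed.
#' @param tank_ids Labels of the tanks to simulate.
#' @return List of [faecal_sample()]s, one per tank.
#' @export
simulate_faeces <- function(diet, true_adcs, noise_cv = 0, seed = 1L,
                            tank_ids = paste0(diet$name, "-", 1:3)) {
  stopifnot(inherits(diet, "diet_spec"))
  need <- c("dm", "protein", "lipid", "phosphorus", "energy")
  stopifnot(all(need %in% names(true_adcs)))
  if (any(true_adcs >= 100)) {
    stop("an ADC of 100% leaves no faecal material to invert; ",
         "true ADCs must be below 100", call. = FALSE)
  }
  d_m <- as_dm_basis(diet$marker, diet$dm)
  d_lev <- c(protein = as_dm_basis(diet$crude_protein, diet$dm),
             lipid = as_dm_basis(diet$crude_fat, diet$dm),
             phosphorus = as_dm_basis(diet$total_p, diet$dm),
             energy = as_dm_basis(diet$gross_energy, diet$dm))
  lapply(tank_ids, function(tid) {
    set.seed(substream_seed(seed, "faeces", tid))
    eps <- stats::setNames(lognorm_factor(length(need), noise_cv), need)
    adc_eff <- 100 - (100 - true_adcs[need]) * eps
    indig <- (100 - adc_eff) / 100
    f_m <- d_m / indig[["dm"]]
    f_lev <- d_lev * indig[names(d_lev)] / indig[["dm"]]
    faecal_sample(tid, protein = f_lev[["protein"]],
                  lipid = f_lev[["lipid"]],
                  phosphorus = f_lev[["phosphorus"]],
                  energy = f_lev[["energy"]], marker = f_m)
  })
}

#' Simulate a qPCR Ct dataset with designed fold-changes
#'
#' Ct values are constructed so that the Pfaffl ratio of noiseless data
#' equals the designed fold-change: each target gene's Ct is its baseline
#' minus log_E(designed fold), reference genes stay at their baseline
#' across all groups, and Gaussian cycle noise is added on top. The
#' designed fold for a growth-period sample is `fold_growth` (relative to
#' the CTRL growth group); for a challenge-period sample it is
#' `fold_growth x fold_post`.
#'
#' @param design Tibble with `gene`, `diet`, `fold_growth`, `fold_post`.
#' @param genes Tibble with `gene`, `efficiency` (%), `role`.
#' @param ct_noise_sd Ct noise SD, cycles.
#' @param seed Integer seed.
#' @param n_replicates Tanks per diet.
#' @param samples_per_tank Sampled fish per tank and period.
#' @param base_ct Named baseline Ct: `target` and `reference` cycles.
#' @param periods Periods to simulate.
#' @return A [qpcr_dataset()].
#' @export
simulate_qpcr <- function(design, genes, ct_noise_sd = 0, seed = 1L,
                          n_replicates = 3, samples_per_tank = 3,
                          base_ct = c(target = 26, reference = 20),
                          periods = c("growth", "challenge")) {
  design <- tibble::as_tibble(design)
  if (any(design$fold_growth <= 0) || any(design$fold_post <= 0)) {
    stop("designed fold-changes must be positive", call. = FALSE)
  }
  diets <- unique(design$diet)
  e <- stats::setNames(1 + genes$efficiency / 100, genes$gene)
  samples <- tidyr::expand_grid(diet = diets, rep = seq_len(n_replicates),
                                period = periods,
                                fish = seq_len(samples_per_tank))
  samples$tank_id <- paste0(samples$diet, "-", samples$rep)
  samples$sample <- paste0(samples$tank_id, ".", samples$period, ".",
                           samples$fish)
  ct <- matrix(NA_real_, nrow = nrow(genes), ncol = nrow(samples),
               dimnames = list(genes$gene, samples$sample))
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    set.seed(substream_seed(seed, "qpcr", s$sample))
    noise <- stats::rnorm(nrow(genes), 0, ct_noise_sd)
    for (i in seq_len(nrow(genes))) {
      g <- genes$gene[i]
      if (genes$role[i] == "reference") {
        fold <- 1
        base <- base_ct[["reference"]]
      } else {
        row <- design[design$gene == g & design$diet == s$diet, ]
        if (nrow(row) == 0L) {
          stop("design lacks gene ", g, " for diet ", s$diet, call. = FALSE)
        }
        fold <- row$fold_growth[1] *
          if (s$period == "challenge") row$fold_post[1] else 1
        base <- base_ct[["target"]]
      }
      ct[i, j] <- base - log(fold) / log(e[[g]]) + noise[i]
    }
  }
  qpcr_dataset(genes = genes,
               samples = samples[, c("sample", "tank_id", "diet",
                                     "period")],
               ct = ct)
}

#' Simulate a complete trial with embedded ground truth
#'
#' Generates tank records (TGC-projected growth with multiplicative
#' lognormal tank noise, binomial mortality, feed distributed = gain x true
#' FCR x noise), faecal samples ([simulate_faeces()]), individual
#' morphometry consistent with the designed somatic indices, whole-body
#' composition pools, and a two-period qPCR dataset
#' ([simulate_qpcr()]). Deterministic for a fixed seed: every tank, sample
#' and gene draws from its own seed substream.
#'
#' @param cfg A [truth_config()].
#' @return A [trial_dataset()] with `truth = cfg` embedded.
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  diets <- cfg$diets
  diet_names <- names(diets)
  tanks <- list()
  faeces <- list()
  morph <- list()
  bc_final <- list()
  for (d in diet_names) {
    w_proj <- project_weight(cfg$ibw, cfg$temperature,
                             cfg$true_tgc[[d]])[cfg$days]
    for (r in seq_len(cfg$n_replicates)) {
      tid <- paste0(d, "-", r)
      set.seed(substream_seed(cfg$seed, "tank", tid))
      p_surv <- stats::runif(1, cfg$survival_range[1],
                             cfg$survival_range[2])
      n_final <- stats::rbinom(1, cfg$n_fish, p_surv)
      fbw <- w_proj * lognorm_factor(1, cfg$growth_noise_cv)
      biomass_initial <- cfg$ibw * cfg$n_fish
      biomass_final <- fbw * n_final
      feed <- n_final * (fbw - cfg$ibw) * cfg$true_fcr[[d]] *
        lognorm_factor(1, cfg$fcr_noise_cv)
      tanks[[tid]] <- tank_record(
        tid, d, cfg$n_fish, n_final, biomass_initial, biomass_final,
        feed, cfg$days, cfg$temperature, period = "growth")

      # individual morphometry consistent with the designed indices
      set.seed(substream_seed(cfg$seed, "morph", tid))
      bw <- fbw * lognorm_factor(cfg$n_sampled_fish, cfg$fish_weight_cv)
      len <- (100 * bw / cfg$true_k[[d]])^(1 / 3)
      morph[[tid]] <- tibble::tibble(
        body_weight = bw, total_length = len,
        viscera_weight = bw * cfg$true_vsi[[d]] / 100,
        liver_weight = bw * cfg$true_hsi[[d]] / 100)

      # final whole-body pool with multiplicative noise; dry matter is
      # floored at protein + lipid + ash (the remainder being other DM)
      set.seed(substream_seed(cfg$seed, "bodycomp", tid))
      tb <- cfg$body_comp_final[[d]]
      nz <- lognorm_factor(6, cfg$composition_noise_cv)
      prot <- tb$protein * nz[2]; lip <- tb$lipid * nz[3]
      ash <- tb$ash * nz[4]
      bc_final[[tid]] <- body_composition(
        "wet", dm = max(tb$dm * nz[1], prot + lip + ash), protein = prot,
        lipid = lip, ash = ash, phosphorus = tb$phosphorus * nz[5],
        energy = tb$energy * nz[6])
    }
    faeces <- c(faeces, simulate_faeces(
      diets[[d]], cfg$true_adc[[d]], cfg$adc_noise_cv, cfg$seed,
      tank_ids = paste0(d, "-", seq_len(cfg$n_replicates))))
  }
  names(faeces) <- vapply(faeces, function(f) f$tank_id, character(1))
  qpcr <- simulate_qpcr(cfg$expression_design, cfg$genes, cfg$ct_noise_sd,
                        cfg$seed, n_replicates = cfg$n_replicates,
                        samples_per_tank = cfg$samples_per_tank)
  trial_dataset(diets = diets, tanks = tanks, faeces = faeces,
                morphometry = morph,
                body_composition = list(initial = cfg$body_comp_initial,
                                        final = bc_final),
                qpcr = qpcr, truth = cfg)
}
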