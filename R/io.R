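# Delimited-text bundle I/O. Dialect: comma-separated, UTF-8, one header
# row, "." decimal. Numeric columns are printed with enough digits that
# re-reading reproduces the written doubles bit-identically.

fmt_precise <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  } else x
}

write_csv_precise <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_precise), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          check.names = FALSE,
                                          fileEncoding = "UTF-8"))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", basename(path), " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a stage result table
#'
#' Writes any tabular stage output (ADC sets, KPI tables, balance tables,
#' expression tables, summaries) as CSV with stable column order and full
#' numeric precision, so re-reading reproduces every double bit-identically.
#' An empty result yields a header-only file.
#'
#' @param results A data frame / tibble produced by a pipeline stage.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  write_csv_precise(results, path)
}

#' Read back a stage result table
#'
#' @param path CSV written by [write_results()].
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Write a trial dataset as a CSV bundle
#'
#' Produces the file set [read_trial_bundle()] reads: diet composition,
#' ingredients, amino-acid profiles, tank records, daily temperatures,
#' faecal composition, morphometry, body-composition pools and the long
#' qPCR table, plus a `config.yaml` tying them together.
#'
#' @param trial A [trial_dataset()].
#' @param dir Output directory (created if needed).
#' @return The config file path, invisibly.
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  comp <- purrr::map_dfr(trial$diets, function(d) {
    tibble::tibble(diet = d$name, dm = d$dm, ash = d$ash,
                   crude_protein = d$crude_protein,
                   crude_fat = d$crude_fat, total_p = d$total_p,
                   gross_energy = d$gross_energy, marker = d$marker)
  })
  write_csv_precise(comp, p("diet_composition.csv"))

  ing <- purrr::map_dfr(trial$diets, function(d) {
    if (is.null(d$ingredients)) return(NULL)
    dplyr::bind_cols(tibble::tibble(diet = d$name), d$ingredients)
  })
  if (nrow(ing)) write_csv_precise(ing, p("diet_ingredients.csv"))

  aa <- purrr::map_dfr(trial$diets, function(d) {
    if (is.null(d$aa_profile)) return(NULL)
    dplyr::bind_cols(tibble::tibble(diet = d$name), d$aa_profile)
  })
  if (nrow(aa)) write_csv_precise(aa, p("aa_profile.csv"))

  write_csv_precise(tanks_table(trial)[, c(
    "tank_id", "diet", "period", "n_initial", "n_final",
    "biomass_initial", "biomass_final", "feed_distributed", "days")],
    p("tanks.csv"))
  temps <- purrr::map_dfr(trial$tanks, function(t) {
    tibble::tibble(tank_id = t$tank_id, day = seq_along(t$temperatures),
                   temp_c = t$temperatures)
  })
  write_csv_precise(temps, p("temperatures.csv"))

  if (!is.null(trial$faeces)) {
    fa <- purrr::map_dfr(trial$faeces, function(f) {
      tibble::tibble(tank_id = f$tank_id, protein = f$protein,
                     lipid = f$lipid, phosphorus = f$phosphorus,
                     energy = f$energy, marker = f$marker)
    })
    write_csv_precise(fa, p("faeces.csv"))
  }
  if (!is.null(trial$morphometry)) {
    mo <- purrr::imap_dfr(trial$morphometry, function(m, tid) {
      dplyr::bind_cols(tibble::tibble(tank_id = tid), m)
    })
    write_csv_precise(mo, p("morphometry.csv"))
  }
  if (!is.null(trial$body_composition)) {
    bc <- trial$body_composition
    rows <- c(list(initial = bc$initial), bc$final)
    bt <- purrr::imap_dfr(rows, function(b, id) {
      tibble::tibble(pool = id, basis = b$basis, dm = b$dm,
                     protein = b$protein, lipid = b$lipid, ash = b$ash,
                     phosphorus = b$phosphorus, energy = b$energy)
    })
    write_csv_precise(bt, p("body_composition.csv"))
  }
  if (!is.null(trial$qpcr)) {
    q <- trial$qpcr
    long <- dplyr::left_join(
      tidyr::pivot_longer(
        dplyr::bind_cols(tibble::tibble(gene = rownames(q$ct)),
                         tibble::as_tibble(q$ct)),
        -"gene", names_to = "sample", values_to = "ct"),
      q$samples, by = "sample")
    long <- dplyr::left_join(long, q$genes, by = "gene")
    write_csv_precise(long[, c("sample", "tank_id", "diet", "period",
                               "gene", "ct", "role", "efficiency")],
                      p("qpcr.csv"))
  }
  cfg <- list(files = list(
    diet_composition = "diet_composition.csv",
    diet_ingredients = if (nrow(ing)) "diet_ingredients.csv",
    aa_profile = if (nrow(aa)) "aa_profile.csv",
    tanks = "tanks.csv", temperatures = "temperatures.csv",
    faeces = if (!is.null(trial$faeces)) "faeces.csv",
    morphometry = if (!is.null(trial$morphometry)) "morphometry.csv",
    body_composition = if (!is.null(trial$body_composition))
      "body_composition.csv",
    qpcr = if (!is.null(trial$qpcr)) "qpcr.csv"))
  cfg$files <- Filter(Negate(is.null), cfg$files)
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(p("config.yaml"))
}

#' Read a trial dataset from a CSV bundle
#'
#' Loads and validates the file set declared in a YAML configuration
#' (paths relative to the config file), reconstructing a fully validated
#' [trial_dataset()]: schemas checked column by column, formulations
#' validated (inclusion sums), tank-to-diet references resolved, qPCR
#' technical duplicates averaged on the Ct scale.
#'
#' @param config Path to a `config.yaml` (as written by
#'   [write_trial_bundle()]) or an equivalent named list with a `files`
#'   element of paths.
#' @param dir Base directory for relative paths; defaults to the config
#'   file's directory.
#' @return A [trial_dataset()].
#' @export
read_trial_bundle <- function(config, dir = NULL) {
  if (is.character(config)) {
    if (is.null(dir)) dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(dir)) dir <- "."
  files <- config$files
  p <- function(key) file.path(dir, files[[key]])

  comp <- read_csv_checked(p("diet_composition"),
                           c("diet", "dm", "ash", "crude_protein",
                             "crude_fat", "total_p", "gross_energy",
                             "marker"), "diet composition")
  ing <- if (!is.null(files$diet_ingredients)) {
    read_csv_checked(p("diet_ingredients"),
                     c("diet", "ingredient", "inclusion"),
                     "diet ingredients")
  }
  aa <- if (!is.null(files$aa_profile)) {
    read_csv_checked(p("aa_profile"),
                     c("diet", "amino_acid", "class", "mg_per_g_dm"),
                     "amino-acid profile")
  }
  diets <- lapply(seq_len(nrow(comp)), function(i) {
    d <- comp[i, ]
    diet_spec(d$diet,
              ingredients = if (!is.null(ing) && any(ing$diet == d$diet))
                ing[ing$diet == d$diet, setdiff(names(ing), "diet")],
              dm = d$dm, ash = d$ash, crude_protein = d$crude_protein,
              crude_fat = d$crude_fat, total_p = d$total_p,
              gross_energy = d$gross_energy, marker = d$marker,
              aa_profile = if (!is.null(aa) && any(aa$diet == d$diet))
                aa[aa$diet == d$diet, setdiff(names(aa), "diet")])
  })
  names(diets) <- comp$diet
  for (d in diets) {
    if (!is.null(d$ingredients)) {
      rep <- validate_formulation(d)
      if (!rep$pass) {
        stop("formulation error in diet '", d$name,
             "': inclusion sum ", sprintf("%.2f", rep$inclusion_sum),
             " != 100", call. = FALSE)
      }
    }
  }

  tk <- read_csv_checked(p("tanks"),
                         c("tank_id", "diet", "period", "n_initial",
                           "n_final", "biomass_initial", "biomass_final",
                           "feed_distributed", "days"), "tank")
  temps <- read_csv_checked(p("temperatures"),
                            c("tank_id", "day", "temp_c"), "temperature")
  tanks <- lapply(seq_len(nrow(tk)), function(i) {
    t <- tk[i, ]
    tt <- temps[temps$tank_id == t$tank_id, ]
    tank_record(t$tank_id, t$diet, t$n_initial, t$n_final,
                t$biomass_initial, t$biomass_final, t$feed_distributed,
                t$days, tt$temp_c[order(tt$day)], period = t$period)
  })

  faeces <- NULL
  if (!is.null(files$faeces)) {
    fa <- read_csv_checked(p("faeces"),
                           c("tank_id", "protein", "lipid", "phosphorus",
                             "energy", "marker"), "faecal composition")
    faeces <- lapply(seq_len(nrow(fa)), function(i) {
      f <- fa[i, ]
      faecal_sample(f$tank_id, f$protein, f$lipid, f$phosphorus, f$energy,
                    f$marker)
    })
    names(faeces) <- fa$tank_id
  }

  morph <- NULL
  if (!is.null(files$morphometry)) {
    mo <- read_csv_checked(p("morphometry"),
                           c("tank_id", "body_weight", "total_length"),
                           "morphometry")
    morph <- lapply(split(mo[setdiff(names(mo), "tank_id")], mo$tank_id),
                    fish_morphometry)
  }

  bc <- NULL
  if (!is.null(files$body_composition)) {
    bt <- read_csv_checked(p("body_composition"),
                           c("pool", "basis", "dm", "protein", "lipid",
                             "ash", "phosphorus", "energy"),
                           "body composition")
    rows <- lapply(seq_len(nrow(bt)), function(i) {
      b <- bt[i, ]
      body_composition(b$basis, dm = b$dm, protein = b$protein,
                       lipid = b$lipid, ash = b$ash,
                       phosphorus = b$phosphorus, energy = b$energy)
    })
    names(rows) <- bt$pool
    if (!"initial" %in% bt$pool) {
      stop("body-composition file lacks the 'initial' pool", call. = FALSE)
    }
    bc <- list(initial = rows[["initial"]],
               final = rows[setdiff(bt$pool, "initial")])
  }

  qpcr <- NULL
  if (!is.null(files$qpcr)) {
    ql <- read_csv_checked(p("qpcr"),
                           c("sample", "tank_id", "diet", "period",
                             "gene", "ct", "role", "efficiency"),
                           "qPCR")
    # average technical duplicates on the Ct scale
    ql <- ql |>
      dplyr::group_by(.data$sample, .data$tank_id, .data$diet,
                      .data$period, .data$gene, .data$role,
                      .data$efficiency) |>
      dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
    genes <- dplyr::distinct(ql[, c("gene", "efficiency", "role")])
    samples <- dplyr::distinct(ql[, c("sample", "tank_id", "diet",
                                      "period")])
    ctm <- matrix(NA_real_, nrow(genes), nrow(samples),
                  dimnames = list(genes$gene, samples$sample))
    ctm[cbind(match(ql$gene, genes$gene),
              match(ql$sample, samples$sample))] <- ql$ct
    qpcr <- qpcr_dataset(genes, samples, ctm)
  }

  trial_dataset(diets = diets, tanks = tanks, faeces = faeces,
                morphometry = morph, body_composition = bc, qpcr = qpcr)
}
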