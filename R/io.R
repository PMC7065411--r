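#' Read and validate weighing records from delimited text
#'
#' Reads a tab-separated record file (header row naming the columns; `#`
#' lines are comments) and validates every row against the domain rules:
#' measurements strictly positive, BCS within 1--5, muscle score within
#' 1--10, lactation days within 1--364 and dry days within -56 to -1,
#' parity a positive integer. Offending rows are rejected with
#' row-numbered messages (collected in attribute `rejected`), the rest
#' returned. Units follow the study conventions: cm for measurements,
#' kg for weight, points for scores.
#'
#' A `genotype` column is taken as-is; otherwise it is derived from
#' `breed` (+ `rh_fraction` for Fleckvieh) via [classify_genotype()].
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param quiet suppress the acceptance/rejection message.
#' @return data.frame of validated records; rejected row messages in
#'   attribute `rejected`.
#' @export
read_records <- function(path, sep = "\t", quiet = FALSE) {
  raw <- utils::read.delim(path, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("cow_id", "farm_id", "parity", "day")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0)
    stop("record file lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!"genotype" %in% names(raw)) {
    if (!"breed" %in% names(raw))
      stop("record file needs a genotype or breed column")
    raw$genotype <- classify_genotype(
      raw$breed, if ("rh_fraction" %in% names(raw)) raw$rh_fraction else NA)
  }

  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf("row %d: %s", rows, what))
    }
    bad & !is.na(bad)
  }
  drop <- rep(FALSE, nrow(raw))
  day <- suppressWarnings(as.numeric(raw$day))
  drop <- drop | flag(is.na(day) | !((day >= 1 & day <= 364) |
                                     (day >= -56 & day <= -1)),
    "day relative to calving outside the lactation (1-364) or dry (-56..-1) domain")
  par <- suppressWarnings(as.numeric(raw$parity))
  drop <- drop | flag(is.na(par) | par < 1 | par != round(par),
                      "parity must be an integer >= 1")
  drop <- drop | flag(!raw$genotype %in% genotype_levels(),
                      "unknown genotype class")
  for (tr in intersect(trait_names(), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[tr]]))
    bad <- !is.na(raw[[tr]]) & (is.na(v) | v <= 0)
    drop <- drop | flag(bad, paste(tr, "must be a positive number"))
    raw[[tr]] <- v
  }
  if ("BCS" %in% names(raw))
    drop <- drop | flag(!is.na(raw$BCS) & (raw$BCS < 1 | raw$BCS > 5),
                        "BCS outside the 1-5 point range")
  if ("MUSC" %in% names(raw))
    drop <- drop | flag(!is.na(raw$MUSC) & (raw$MUSC < 1 | raw$MUSC > 10),
                        "muscle score outside the 1-10 point range")
  if ("bw" %in% names(raw)) {
    v <- suppressWarnings(as.numeric(raw$bw))
    drop <- drop | flag(!is.na(raw$bw) & (is.na(v) | v <= 0),
                        "bw must be a positive number")
    raw$bw <- v
  }

  out <- raw[!drop, , drop = FALSE]
  out$day <- as.numeric(out$day)
  out$parity <- as.numeric(out$parity)
  out$parity_class <- classify_parity(out$parity)
  if (!quiet)
    message(nrow(out), " record(s) accepted, ", sum(drop), " rejected")
  attr(out, "rejected") <- problems
  out
}

#' Write weighing records to delimited text
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces them exactly.
#'
#' @param records data.frame of records.
#' @param path file path.
#' @param header optional character vector of provenance lines, written as
#'   `#` comments before the table.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, header = NULL) {
  records <- as.data.frame(records)
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = 17, format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @details `write_herd()`/`read_herd()` add a provenance header (seed,
#'   generator settings) and keep the `.farm_effect`/`.residual` columns,
#'   so a simulated herd survives serialization with its generating
#'   identity intact.
#' @param herd a `cow_herd` from [simulate_herd()].
#' @export
write_herd <- function(herd, path) {
  cfg <- attr(herd, "config")
  header <- c("synthetic herd generated by cowbw::simulate_herd")
  if (!is.null(cfg)) {
    header <- c(header,
                paste0("seed: ", cfg$seed),
                paste0("truth: ", cfg$truth$name),
                paste0("farm_sd: ", cfg$farm_sd,
                       " residual_sd: ", cfg$residual_sd),
                paste0("n_farms: ", cfg$n_farms,
                       " cows_per_farm: ",
                       paste(cfg$cows_per_farm, collapse = "-"),
                       " records_per_cow: ", cfg$records_per_cow))
  }
  write_records(as.data.frame(herd), path, header = header)
}

#' @rdname write_records
#' @export
read_herd <- function(path) {
  read_records(path, quiet = TRUE)
}

#' Run the full simulate-split-fit-validate pipeline
#'
#' Orchestrates one end-to-end run: simulate a herd (or read records from
#' `records_path`), split off the every-fifth-record validation subset,
#' fit the mixed model on the estimation subset, assemble the continuous
#' prediction equation and validate it on the hold-out records. All
#' artifacts (herd, fitted equation, validation table, manifest with
#' content hashes and the seed) are written to `out_dir`; an identical
#' configuration reproduces identical numeric artifacts.
#'
#' @param sim a [sim_config()], ignored when `records_path` is given.
#' @param spec a [model_spec()]; default: genotype-specific slopes on the
#'   measurements of `sim$truth`. Set `fit = FALSE` to skip estimation
#'   and validate a packaged equation (`coeffs`) directly.
#' @param records_path optional path to an existing record file.
#' @param out_dir output directory (created if missing).
#' @param fit whether to re-estimate the equation (otherwise `coeffs` is
#'   validated as-is).
#' @param coeffs equation to validate when `fit = FALSE`.
#' @param split `"every_fifth"` (the study rule) or `"cow_level"`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `herd`, `split`, `fit`, `coefficients`,
#'   `validation` and the artifact `paths`.
#' @export
run_pipeline <- function(sim = sim_config(), spec = NULL,
                         records_path = NULL, out_dir = tempfile("cowbw_run_"),
                         fit = TRUE, coeffs = NULL,
                         split = c("every_fifth", "cow_level"),
                         quiet = FALSE) {
  split <- match.arg(split)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(records_path)) {
      say("simulating herd (seed ", sim$seed, ") ...")
      herd <- simulate_herd(sim)
      herd_path <- file.path(out_dir, "herd.tsv")
      write_herd(herd, herd_path)
    } else {
      say("reading records from ", records_path, " ...")
      herd <- read_records(records_path, quiet = quiet)
      herd_path <- records_path
    }

    stage <- "split"
    parts <- if (split == "every_fifth") split_every_fifth(herd)
             else split_cow_level(herd, 0.2, seed = sim$seed)

    stage <- "fit"
    fit_obj <- NULL
    if (fit) {
      if (is.null(spec)) {
        truth_ms <- if (!is.null(attr(herd, "config")))
          attr(herd, "config")$truth$model_spec else sim$truth$model_spec
        spec <- model_spec(truth_ms, genotype_specific = TRUE)
      }
      say("fitting mixed model (", paste(spec$measurements, collapse = "+"),
          ") on ", nrow(parts$estimation), " records ...")
      fit_obj <- fit_mixed(parts$estimation, spec)
      coeffs <- fit_obj$coefficients
    } else if (is.null(coeffs)) {
      stop("fit = FALSE requires a coefficient set in 'coeffs'")
    }
    model_path <- file.path(out_dir, "model.yml")
    write_coefficient_set(coeffs, model_path)

    stage <- "validate"
    say("validating on ", nrow(parts$validation), " held-out records ...")
    val <- validate_model(coeffs, parts$validation)
    val_path <- file.path(out_dir, "validation.tsv")
    write_records(as.data.frame(val), val_path)

    stage <- "manifest"
    files <- c(herd = herd_path, model = model_path, validation = val_path)
    manifest <- list(
      seed = sim$seed,
      split = split,
      fitted = fit,
      package_version = as.character(utils::packageVersion("cowbw")),
      files = lapply(stats::setNames(as.list(files), names(files)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))))
    manifest_path <- file.path(out_dir, "manifest.yml")
    writeLines(yaml::as.yaml(manifest), manifest_path)

    list(herd = herd, split = parts, fit = fit_obj, coefficients = coeffs,
         validation = val,
         paths = c(files, manifest = manifest_path))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
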