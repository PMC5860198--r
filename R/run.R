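#' Run configuration for a reproducible DFS scan
#'
#' Collects every knob of the pipeline; the snapshot written alongside the
#' outputs is sufficient to re-run a scan bit-identically.
#'
#' @param input Path to a PDB file (or a TSV node table ending in `.tsv`).
#' @param chain Chain selection (default `"ALL"`).
#' @param model Model number (default 1).
#' @param r_c,gamma,n_orientations,magnitude,schemes,percentile,zero_tol
#'   Pipeline parameters, see [dfs()].
#' @param out_prefix Output path prefix for all generated files.
#' @param seed Integer seed recorded in the snapshot (the scan itself is
#'   deterministic; the seed governs fixture generation workflows).
#' @return A `dfs_config` list.
#' @export
dfs_config <- function(input, chain = "ALL", model = 1L, r_c = 15, gamma = 1,
                       n_orientations = 12, magnitude = 1,
                       schemes = c("FF", "FR"), percentile = 0.28,
                       zero_tol = 1e-6, out_prefix = "dfs", seed = NULL) {
  structure(
    list(
      input = input, chain = chain, model = model, r_c = r_c, gamma = gamma,
      n_orientations = n_orientations, magnitude = magnitude,
      schemes = schemes, percentile = percentile, zero_tol = zero_tol,
      out_prefix = out_prefix, seed = seed
    ),
    class = "dfs_config"
  )
}

# full-precision numeric formatting so rewritten TSVs are bit-identical
fmt_num <- function(x) {
  ifelse(is.na(x), "NaN", sprintf("%.17g", x))
}

#' Write a rescuability matrix as dense TSV
#'
#' Residue keys as header and first column; the masked diagonal is encoded
#' as NaN. Values carry full double precision so a rewrite is
#' bit-identical.
#'
#' @param m A `rescuability_matrix`.
#' @param path File path.
#' @return `path` (write) or a `rescuability_matrix` (read).
#' @export
write_rescuability_tsv <- function(m, path) {
  lines <- c(
    paste(c("key", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rescuability_tsv
#' @param scheme Scheme tag to attach on read.
#' @export
read_rescuability_tsv <- function(path, scheme = NA_character_) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, na.strings = "NaN")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("rescuability_matrix", "matrix", "array"), scheme = scheme)
}

#' Execute a scan from a run configuration
#'
#' Reads the structure, runs [dfs()] and writes, under the configured
#' prefix: one rescuability matrix TSV per scheme, the per-residue profile
#' TSV (with the predicted-site flag), the C-alpha node table, a JSON
#' config snapshot and a run log. Re-running the same snapshot reproduces
#' every file bit-identically.
#'
#' @param config A [dfs_config()].
#' @return The `dfs_result`, invisibly; the written file paths are in
#'   attribute `files`.
#' @export
run_scan <- function(config) {
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  s <- withCallingHandlers(
    if (grepl("\\.tsv$", config$input)) {
      read_structure_tsv(config$input)
    } else {
      read_calpha_structure(config$input, config$chain, config$model)
    },
    warning = function(w) {
      note("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  note("residues read: ", nrow(s))

  res <- dfs(s,
    r_c = config$r_c, gamma = config$gamma,
    n_orientations = config$n_orientations, magnitude = config$magnitude,
    schemes = config$schemes, percentile = config$percentile,
    zero_tol = config$zero_tol
  )

  prefix <- config$out_prefix
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sch in names(res$S)) {
    f <- paste0(prefix, "_S_", sch, ".tsv")
    write_rescuability_tsv(res$S[[sch]], f)
    files <- c(files, f)
  }

  prof <- res$profile
  prof_out <- prof
  for (cl in grep("^component_|^P$", names(prof_out), value = TRUE)) {
    prof_out[[cl]] <- fmt_num(prof_out[[cl]])
  }
  prof_out$predicted <- as.integer(prof$predicted)
  f_prof <- paste0(prefix, "_profile.tsv")
  write.table(prof_out, f_prof, sep = "\t", quote = FALSE, row.names = FALSE)

  f_struct <- paste0(prefix, "_structure.tsv")
  write_structure_tsv(s, f_struct)

  f_cfg <- paste0(prefix, "_config.json")
  cfg <- unclass(config)
  cfg$threshold <- attr(prof, "threshold")
  jsonlite::write_json(cfg, f_cfg, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  note("predicted rescue sites: ", sum(prof$predicted))
  f_log <- paste0(prefix, "_log.txt")
  writeLines(log_lines, f_log)

  attr(res, "files") <- c(files, f_prof, f_struct, f_cfg, f_log)
  invisible(res)
}

#' Evaluate a finished scan against reference sites
#'
#' Loads a scan's output files and a reference site table and computes the
#' confusion summary, the D-minimizing threshold, the proximity categories
#' of reference rescue sites, per-pathogenic-site rescue sets, and (when a
#' pockets table is given) the rescue-pocket classification. Reference
#' residues that do not resolve against the structure are listed; the run
#' fails if more than half are unresolvable.
#'
#' @param prefix Output prefix of a previous [run_scan()].
#' @param reference_path Reference sites TSV.
#' @param pockets_path Optional pockets TSV.
#' @param cutoff Proximity cutoff in Angstrom (default 4).
#' @param percentile Optional re-classification percentile (default: the
#'   one stored in the profile).
#' @return List with `metrics`, `optimal`, `proximity`, `per_ps`,
#'   `pockets` (NULL if not given), `unresolved`.
#' @export
run_evaluate <- function(prefix, reference_path, pockets_path = NULL,
                         cutoff = 4, percentile = NULL) {
  prof <- tibble::as_tibble(read.delim(paste0(prefix, "_profile.tsv"),
    sep = "\t",
    colClasses = c(chain = "character", icode = "character", aa = "character"),
    na.strings = NULL
  ))
  s <- read_structure_tsv(paste0(prefix, "_structure.tsv"))
  reference <- read_reference_sites(reference_path)

  unresolved <- setdiff(reference$key, prof$key)
  if (length(unresolved) > 0.5 * nrow(reference)) {
    stop(
      length(unresolved), "/", nrow(reference),
      " reference residues unresolvable against the profile",
      call. = FALSE
    )
  }
  reference <- reference[reference$key %in% prof$key, ]

  if (!is.null(percentile)) {
    prof <- classify_rescue_sites(prof, percentile)
    prof$predicted <- as.integer(prof$predicted)
  }
  predicted <- prof$key[prof$predicted == 1]

  metrics <- confusion_metrics(predicted, reference, nrow(prof))
  optimal <- optimal_threshold(
    prof$P, prof$key %in% reference_rescue_keys(reference)
  )
  proximity <- proximity_rescue(predicted, reference, s, cutoff)

  s_mats <- list()
  for (sch in c("FF", "FR")) {
    f <- paste0(prefix, "_S_", sch, ".tsv")
    if (file.exists(f)) s_mats[[sch]] <- read_rescuability_tsv(f, sch)
  }
  ps_keys <- reference_pathogenic_keys(reference)
  per_ps <- purrr::map_dfr(ps_keys, function(k) {
    if (!k %in% rownames(s_mats[[1]])) {
      return(tibble::tibble(ps = k, rescue_site = NA_character_))
    }
    rs <- pair_specific_rescue(s_mats, k, predicted)
    if (length(rs) == 0L) {
      tibble::tibble(ps = k, rescue_site = NA_character_)
    } else {
      tibble::tibble(ps = k, rescue_site = rs)
    }
  })

  pockets <- NULL
  if (!is.null(pockets_path)) {
    pockets <- pocket_classification(read_pockets(pockets_path), predicted)
  }

  list(
    metrics = metrics, optimal = optimal, proximity = proximity,
    per_ps = per_ps, pockets = pockets, unresolved = unresolved
  )
}
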