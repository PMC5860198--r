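#' Confusion metrics of a rescue-site prediction
#'
#' Exact residue-key matching of a predicted site set against a reference
#' rescue-site set. Enrichment is the probability of finding a true rescue
#' site among the predictions relative to a random guess:
#' `(TP/(TP+FP)) / ((TP+FN)/nres)`; it is reported as NA when there are no
#' predictions.
#'
#' @param predicted Character vector of predicted residue keys.
#' @param reference A reference site table (tibble with `key` and `label`
#'   columns, labels in `PS`/`RS`/`PS+RS`), or a character vector of
#'   rescue-site keys.
#' @param nres Total number of residues in the structure.
#' @return One-row tibble: `TP`, `FP`, `FN`, `TN`, `nres`, `sensitivity`,
#'   `specificity`, `accuracy`, `enrichment`.
#' @export
confusion_metrics <- function(predicted, reference, nres) {
  pos <- reference_rescue_keys(reference)
  if (length(pos) == 0L) stop("empty reference rescue-site set", call. = FALSE)
  predicted <- unique(predicted)
  tp <- sum(predicted %in% pos)
  fp <- length(predicted) - tp
  fn <- length(pos) - tp
  tn <- nres - tp - fp - fn
  if (tn < 0) stop("nres smaller than the union of sets", call. = FALSE)
  enr <- if (tp + fp == 0L) NA_real_ else (tp / (tp + fp)) / ((tp + fn) / nres)
  tibble::tibble(
    TP = tp, FP = fp, FN = fn, TN = tn, nres = nres,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / nres,
    enrichment = enr
  )
}

# Accepts a reference tibble (label column) or a plain key vector and
# returns the rescue-site keys.
reference_rescue_keys <- function(reference) {
  if (is.data.frame(reference)) {
    if (!"key" %in% names(reference)) {
      reference$key <- res_key(
        reference$chain, reference$resnum,
        if ("icode" %in% names(reference)) reference$icode else ""
      )
    }
    if ("label" %in% names(reference)) {
      reference$key[grepl("RS", reference$label)]
    } else {
      reference$key
    }
  } else {
    as.character(reference)
  }
}

# Same, for pathogenic sites.
reference_pathogenic_keys <- function(reference) {
  if (is.data.frame(reference)) {
    if (!"key" %in% names(reference)) {
      reference$key <- res_key(
        reference$chain, reference$resnum,
        if ("icode" %in% names(reference)) reference$icode else ""
      )
    }
    if ("label" %in% names(reference)) {
      reference$key[grepl("PS", reference$label)]
    } else {
      character(0)
    }
  } else {
    character(0)
  }
}

#' Optimal classification threshold minimizing D
#'
#' Scans every distinct score value as a candidate strict threshold
#' (`score > t` predicts positive) and returns the one minimizing
#' `D = (1 - sensitivity)^2 + (1 - specificity)^2`; ties are resolved in
#' favour of the threshold admitting fewer predicted positives.
#'
#' @param score Per-residue scores (e.g. compensatory power P).
#' @param is_positive Logical reference labels, same length; needs at least
#'   one positive and one negative.
#' @return One-row tibble: `threshold`, `D`, `sensitivity`, `specificity`,
#'   `n_predicted`.
#' @export
optimal_threshold <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive))
  npos <- sum(is_positive)
  nneg <- sum(!is_positive)
  if (npos == 0L || nneg == 0L) {
    stop("need at least one positive and one negative reference label", call. = FALSE)
  }
  cand <- sort(unique(score))
  stats <- purrr::map_dfr(cand, function(t) {
    pred <- score > t
    tibble::tibble(
      threshold = t,
      sensitivity = sum(pred & is_positive) / npos,
      specificity = sum(!pred & !is_positive) / nneg,
      n_predicted = sum(pred)
    )
  })
  stats$D <- (1 - stats$sensitivity)^2 + (1 - stats$specificity)^2
  stats <- stats[order(stats$D, stats$n_predicted), ]
  stats[1, c("threshold", "D", "sensitivity", "specificity", "n_predicted")]
}

#' Proximity analysis of reference rescue sites
#'
#' Labels each reference rescue site as `predicted` (exact match with the
#' predicted set), `contact` (minimum heavy-atom distance to any predicted
#' site below the cutoff) or `missed`. When heavy-atom coordinates are not
#' stored the C-alpha fallback distance is used with its own (wider)
#' default cutoff and the rows are flagged.
#'
#' @param predicted Character vector of predicted residue keys.
#' @param reference Reference site table or rescue-key vector (see
#'   [confusion_metrics()]).
#' @param s The [cg_structure()] the keys refer to.
#' @param cutoff Heavy-atom contact cutoff in Angstrom (default 4).
#' @param calpha_cutoff Cutoff used when falling back to C-alpha-only
#'   distances (default 8).
#' @return Tibble with `key`, `category`, `min_dist`, `calpha_fallback`.
#' @export
proximity_rescue <- function(predicted, reference, s, cutoff = 4,
                             calpha_cutoff = 8) {
  pos <- reference_rescue_keys(reference)
  keys <- cg_keys(s)
  pred_idx <- match(intersect(predicted, keys), keys)
  purrr::map_dfr(pos, function(k) {
    i <- match(k, keys)
    if (is.na(i)) {
      return(tibble::tibble(
        key = k, category = "unresolved",
        min_dist = NA_real_, calpha_fallback = NA
      ))
    }
    if (k %in% predicted) {
      return(tibble::tibble(
        key = k, category = "predicted",
        min_dist = 0, calpha_fallback = FALSE
      ))
    }
    others <- setdiff(pred_idx, i)
    if (length(others) == 0L) {
      return(tibble::tibble(
        key = k, category = "missed",
        min_dist = NA_real_, calpha_fallback = NA
      ))
    }
    d <- vapply(others, function(j) min_heavy_atom_distance(s, i, j), numeric(1))
    fb <- any(vapply(
      others,
      function(j) isTRUE(attr(min_heavy_atom_distance(s, i, j), "calpha_fallback")),
      logical(1)
    ))
    eff_cut <- if (fb) calpha_cutoff else cutoff
    tibble::tibble(
      key = k,
      category = if (min(d) < eff_cut) "contact" else "missed",
      min_dist = min(d), calpha_fallback = fb
    )
  })
}

#' Predicted rescue sites for one pathogenic site
#'
#' A site j is considered to potentially rescue pathogenic site i if its
#' rescuability score `S_ij` is positive under either scheme; by default
#' the result is intersected with the globally classified rescue-site set
#' (a site must first qualify as a predicted rescue site). Set
#' `restrict = FALSE` for the looser score-only variant.
#'
#' @param s_matrices Named list of `rescuability_matrix` objects.
#' @param i Pathogenic site: residue key or row index.
#' @param predicted Character vector of classified rescue-site keys (used
#'   when `restrict = TRUE`).
#' @param restrict Intersect with `predicted`? Default TRUE.
#' @return Character vector of rescue-site keys for site i.
#' @export
pair_specific_rescue <- function(s_matrices, i, predicted = NULL,
                                 restrict = TRUE) {
  m1 <- s_matrices[[1]]
  keys <- colnames(m1)
  if (is.character(i)) {
    idx <- match(i, rownames(m1))
    if (is.na(idx)) stop("site ", i, " not in matrix", call. = FALSE)
  } else {
    idx <- i
  }
  hit <- rep(FALSE, length(keys))
  for (m in s_matrices) {
    row <- m[idx, ]
    hit <- hit | (!is.na(row) & row > 0)
  }
  out <- keys[hit]
  if (restrict) {
    if (is.null(predicted)) stop("`predicted` required when restrict = TRUE", call. = FALSE)
    out <- intersect(out, predicted)
  }
  setdiff(out, keys[idx])
}

#' Classify binding pockets as rescue pockets
#'
#' A pocket is a rescue pocket if at least `threshold` (default 20%) of its
#' member residues are rescue sites. Pockets are ranked by decreasing
#' rescue-site content, ties stable by pocket id.
#'
#' @param pockets Long tibble with one row per member: `pocket_id` plus
#'   either a `key` column or `chain`/`resnum`(/`icode`) columns.
#' @param rescue_sites Character vector of rescue-site keys.
#' @param threshold Inclusive rescue-content threshold (default 0.20).
#' @return Tibble with `pocket_id`, `n_members`, `pct_RS`, `is_rescue_pocket`.
#' @export
pocket_classification <- function(pockets, rescue_sites, threshold = 0.20) {
  pockets <- tibble::as_tibble(pockets)
  if (!"key" %in% names(pockets)) {
    pockets$key <- res_key(
      pockets$chain, pockets$resnum,
      if ("icode" %in% names(pockets)) pockets$icode else ""
    )
  }
  if (any(is.na(pockets$key) | pockets$key == "")) {
    stop("pocket with unresolvable/empty members", call. = FALSE)
  }
  out <- pockets |>
    dplyr::group_by(.data$pocket_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      pct_RS = mean(.data$key %in% rescue_sites),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_rescue_pocket = .data$pct_RS >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$pct_RS), .data$pocket_id)
  out
}

#' Root mean square inner product of a motion with a mode set
#'
#' Overlap of a (unit-normalized) displacement vector with k orthonormal
#' normal modes: `RMSIP = sqrt(sum_k (v . m_k)^2)`, together with the
#' per-mode squared inner products. Invariant to the sign and scale of the
#' motion and to sign flips of individual modes; equals 1 when the motion
#' lies entirely inside the mode subspace (Parseval).
#'
#' @param motion 3N displacement vector (non-zero).
#' @param modes A `mode_spectrum` from [normal_modes()], or a 3N x k matrix
#'   of orthonormal mode vectors.
#' @return List with `rmsip` (scalar) and `per_mode` (length-k vector of
#'   squared inner products).
#' @export
rmsip <- function(motion, modes) {
  if (all(motion == 0)) stop("zero motion vector", call. = FALSE)
  m <- if (inherits(modes, "mode_spectrum")) modes$vectors else modes
  v <- motion / sqrt(sum(motion^2))
  ip2 <- as.vector(crossprod(m, v))^2
  list(rmsip = sqrt(sum(ip2)), per_mode = ip2)
}

#' Divergent positions of a pairwise alignment
#'
#' Columns of an aligned sequence pair where both characters are standard
#' amino acids and differ (case-insensitive); gap-containing columns are
#' skipped (insertions/deletions are not point compensations). Positions
#' are reported in the ungapped numbering of the first (human) sequence.
#'
#' @param human,homologue Aligned sequences of equal length (character
#'   strings).
#' @return Increasing integer vector of divergent positions.
#' @export
divergent_positions <- function(human, homologue) {
  a <- toupper(strsplit(human, "")[[1]])
  b <- toupper(strsplit(homologue, "")[[1]])
  if (length(a) != length(b)) {
    stop("aligned sequences have different lengths", call. = FALSE)
  }
  std <- names(.aa1)
  human_pos <- cumsum(a %in% c(std, setdiff(LETTERS, std))) # ungapped index
  ok <- a %in% std & b %in% std & a != b
  human_pos[ok]
}

#' Read a pairwise alignment from an aligned FASTA file
#'
#' Expects exactly two records of equal aligned length; the first is taken
#' as the human sequence.
#'
#' @param path Aligned FASTA file.
#' @return Character vector of length 2 (named by record id).
#' @export
read_pairwise_alignment <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read alignment FASTA", call. = FALSE)
  }
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) != 2L) {
    stop("alignment must contain exactly 2 records, found ", length(aln),
      call. = FALSE
    )
  }
  w <- Biostrings::width(aln)
  if (w[1] != w[2]) stop("aligned sequences have different lengths", call. = FALSE)
  setNames(as.character(aln), names(aln))
}
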