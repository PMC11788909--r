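# Relatedness-based pedigree correction.
#
# Two moves, applied in a fixed order: (1) exclusion of individuals whose
# realized relatedness to every other sampled individual is low (field
# mislabels unrelated to the whole collection), then (2) reassignment of
# individuals whose mean relatedness to another family's members is
# clearly above their own family's (labels swapped between families).
# Both thresholds are explicit parameters anchored on the half-sib
# expectation of 0.25; the procedure is a deterministic single pass.

#' Pedigree-correction configuration
#'
#' @param unrelated_threshold an individual is excluded when its maximum
#'   off-diagonal relatedness to any other individual is below this
#'   (default 0.1).
#' @param reassign_threshold minimum mean relatedness to the best other
#'   family required to move an individual (default 0.125, half the
#'   half-sib expectation).
#' @param margin the best-family mean must exceed the own-family mean by at
#'   least this much (default 0.1); ties therefore never move.
#' @return an object of class `correction_config`.
#' @export
correction_config <- function(unrelated_threshold = 0.1,
                              reassign_threshold = 0.125,
                              margin = 0.1) {
  stopifnot(unrelated_threshold >= 0, reassign_threshold >= 0, margin >= 0)
  structure(list(unrelated_threshold = unrelated_threshold,
                 reassign_threshold = reassign_threshold,
                 margin = margin),
            class = "correction_config")
}

#' Flag individuals unrelated to every other sampled individual
#'
#' @param grm a [vanraden_grm()] covering the pedigree.
#' @param pedigree `data.frame` with `individual_id` and `family_id`.
#' @param config a [correction_config()].
#' @return a `data.frame` with `individual_id` and `max_r` for every
#'   flagged individual (zero rows when none).
#' @export
flag_unrelated <- function(grm, pedigree, config = correction_config()) {
  stopifnot(inherits(grm, "grm"))
  ids <- pedigree$individual_id
  missing_ids <- setdiff(ids, grm$individual_ids)
  if (length(missing_ids))
    stop("pedigree individuals absent from GRM: ",
         paste(missing_ids, collapse = ", "))
  G <- grm$matrix[ids, ids, drop = FALSE]
  diag(G) <- -Inf
  max_r <- apply(G, 1L, max)
  flagged <- max_r < config$unrelated_threshold
  data.frame(individual_id = ids[flagged], max_r = unname(max_r[flagged]),
             stringsAsFactors = FALSE)
}

#' Reassign individuals to better-supported families
#'
#' For each individual (exclusions already removed), the mean relatedness
#' to each family's other members is computed; the individual moves to the
#' best family iff that mean is at least `reassign_threshold` and exceeds
#' the own-family mean by at least `margin`.  Individuals are evaluated in
#' id order against the *original* assignments (single pass, no cascading).
#'
#' @param grm a [vanraden_grm()].
#' @param pedigree pedigree `data.frame` after exclusions.
#' @param config a [correction_config()].
#' @return a list: `pedigree` (corrected), `moves` (`data.frame` with
#'   `individual_id`, `old_family`, `new_family`, `own_mean_r`,
#'   `best_mean_r`).
#' @export
reassign_individuals <- function(grm, pedigree, config = correction_config()) {
  stopifnot(inherits(grm, "grm"))
  ped <- pedigree[order(pedigree$individual_id), , drop = FALSE]
  G <- grm$matrix
  fams <- sort(unique(ped$family_id))
  members <- lapply(setNames(fams, fams), function(f)
    ped$individual_id[ped$family_id == f])
  moves <- list()
  new_family <- setNames(ped$family_id, ped$individual_id)
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    own <- ped$family_id[i]
    mean_to <- vapply(fams, function(f) {
      others <- setdiff(members[[f]], id)
      if (!length(others)) return(NA_real_)
      mean(G[id, others])
    }, 0)
    own_mean <- mean_to[[own]]
    cand <- mean_to[setdiff(fams, own)]
    cand <- cand[!is.na(cand)]
    if (!length(cand)) next
    best <- names(cand)[which.max(cand)]   # first max = family id order
    best_mean <- cand[[best]]
    own_cmp <- if (is.na(own_mean)) -Inf else own_mean
    if (best_mean >= config$reassign_threshold &&
        best_mean - own_cmp >= config$margin &&
        best_mean > own_cmp) {
      new_family[id] <- best
      moves[[length(moves) + 1L]] <- data.frame(
        individual_id = id, old_family = own, new_family = best,
        own_mean_r = own_mean, best_mean_r = best_mean,
        stringsAsFactors = FALSE)
    }
  }
  ped$family_id <- unname(new_family[ped$individual_id])
  out_moves <- if (length(moves)) do.call(rbind, moves) else
    data.frame(individual_id = character(), old_family = character(),
               new_family = character(), own_mean_r = numeric(),
               best_mean_r = numeric(), stringsAsFactors = FALSE)
  list(pedigree = ped, moves = out_moves)
}

#' Full pedigree correction: exclusion then reassignment
#'
#' @param grm a [vanraden_grm()].
#' @param pedigree pedigree `data.frame` with `individual_id`, `family_id`.
#' @param config a [correction_config()].
#' @return a list of class `correction_result`: `pedigree` (corrected, flagged
#'   individuals removed), `excluded`, `moves`, `before` / `after`
#'   ([family_mean_relatedness()] summaries on the original family id set).
#' @export
correct_pedigree <- function(grm, pedigree, config = correction_config()) {
  before <- family_mean_relatedness(grm, pedigree)
  excluded <- flag_unrelated(grm, pedigree, config)
  kept <- pedigree[!pedigree$individual_id %in% excluded$individual_id, ,
                   drop = FALSE]
  re <- reassign_individuals(grm, kept, config)
  after_ped <- re$pedigree
  # keep emptied families visible in the after-summary
  empty <- setdiff(unique(pedigree$family_id), unique(after_ped$family_id))
  after <- family_mean_relatedness(grm, after_ped)
  if (length(empty)) {
    after <- rbind(after, data.frame(family_id = empty, n_members = 0L,
                                     n_pairs = 0L, mean_r = NA_real_,
                                     sd_r = NA_real_))
    class(after) <- c("family_summary", "data.frame")
  }
  after <- after[match(unique(pedigree$family_id), after$family_id), ,
                 drop = FALSE]
  rownames(after) <- NULL
  structure(list(pedigree = after_ped, excluded = excluded,
                 moves = re$moves, before = before, after = after),
            class = "correction_result")
}

#' Side-by-side before/after correction report
#'
#' @param result a [correct_pedigree()] result.
#' @return a `data.frame`: per family, member counts and
#'   `mean r +/- SD` before (BPC) and after (APC) correction.
#' @export
correction_report <- function(result) {
  stopifnot(inherits(result, "correction_result"))
  b <- result$before
  a <- result$after[match(b$family_id, result$after$family_id), ]
  data.frame(family_id = b$family_id,
             n_before = b$n_members, mean_r_bpc = b$mean_r, sd_r_bpc = b$sd_r,
             n_after = a$n_members, mean_r_apc = a$mean_r, sd_r_apc = a$sd_r,
             stringsAsFactors = FALSE)
}

#' @exportS3Method print correction_result
print.correction_result <- function(x, ...) {
  cat("pedigree correction:", nrow(x$excluded), "excluded,",
      nrow(x$moves), "reassigned\n")
  print(correction_report(x))
  invisible(x)
}
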