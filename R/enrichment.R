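#' Screening count summary
#'
#' @param active_hits,decoy_hits hits by class after the pharmacophore
#'   search.
#' @param actives_total,decoys_total library composition.
#' @return An object of class `ph4_counts`.
#' @export
screen_counts <- function(active_hits, decoy_hits, actives_total,
                          decoys_total) {
  if (actives_total <= 0 || decoys_total <= 0)
    stop("library totals must be positive")
  if (active_hits < 0 || active_hits > actives_total)
    stop("active_hits out of range")
  if (decoy_hits < 0 || decoy_hits > decoys_total)
    stop("decoy_hits out of range")
  structure(list(active_hits = active_hits, decoy_hits = decoy_hits,
                 actives_total = actives_total,
                 decoys_total = decoys_total),
            class = "ph4_counts")
}

#' Hit-ratio enrichment factor
#'
#' `EF = (active_hits / decoy_hits) / (actives_total / decoys_total)`:
#' the active:decoy ratio among hits relative to the ratio in the whole
#' library. EF = 1 means hits mirror the library composition. Edge cases
#' are flagged, never silently infinite: no decoy hits with some active
#' hits gives an `Inf` sentinel (flag `"no-decoy-hits"`), no active hits
#' gives 0, and an empty hit list gives `NA` (flag `"NA"`).
#'
#' Note this is the hit-ratio form, not the common top-x% enrichment;
#' see [enrichment_at_fraction()] for the conventional variant.
#'
#' @param counts a [screen_counts()].
#' @return list with `ef` and `flag` (`"ok"`, `"no-decoy-hits"`,
#'   `"no-active-hits"`, `"NA"`).
#' @export
enrichment_factor <- function(counts) {
  stopifnot(inherits(counts, "ph4_counts"))
  a <- counts$active_hits; d <- counts$decoy_hits
  if (a == 0 && d == 0) return(list(ef = NA_real_, flag = "NA"))
  if (a == 0) return(list(ef = 0, flag = "no-active-hits"))
  if (d == 0) return(list(ef = Inf, flag = "no-decoy-hits"))
  list(ef = (a / d) / (counts$actives_total / counts$decoys_total),
       flag = "ok")
}

#' Conventional enrichment at a ranked fraction of the library
#'
#' Clearly-labelled extra, off the main reporting path: molecules are
#' ranked by match RMSD (unmatched last) and the enrichment of actives in
#' the top `fraction` of the ranked library is computed as
#' `(actives in top / n_top) / (actives_total / n_total)`.
#'
#' @param screen a `ph4_screen`.
#' @param fraction top fraction of the ranked library (e.g. 0.01).
#' @return The EF at that fraction.
#' @export
enrichment_at_fraction <- function(screen, fraction = 0.01) {
  stopifnot(inherits(screen, "ph4_screen"), fraction > 0, fraction <= 1)
  r <- screen$results
  ord <- order(!r$matched, r$rmsd)
  n_top <- max(1L, floor(fraction * nrow(r)))
  top <- r[ord[seq_len(n_top)], ]
  frac_top <- mean(top$activity == "active")
  frac_all <- mean(r$activity == "active")
  frac_top / frac_all
}

#' Tally a screen into counts, EF and per-class hit lists
#'
#' Molecules with an activity class other than active/decoy are counted
#' separately, excluded from the EF, and warned about.
#'
#' @param screen a `ph4_screen` from [search_library()].
#' @return list: `counts` ([screen_counts()]), `ef`, `flag`,
#'   `active_hits`, `decoy_hits` (ids), `unknown` (ids of unclassified
#'   molecules).
#' @export
screening_report <- function(screen) {
  stopifnot(inherits(screen, "ph4_screen"))
  r <- screen$results
  known <- r$activity %in% c("active", "decoy")
  if (any(!known))
    warning(sum(!known), " molecules with unknown activity class ",
            "excluded from the enrichment factor")
  rk <- r[known, , drop = FALSE]
  a_hit <- sum(rk$matched & rk$activity == "active")
  d_hit <- sum(rk$matched & rk$activity == "decoy")
  a_tot <- sum(rk$activity == "active")
  d_tot <- sum(rk$activity == "decoy")
  if (d_tot == 0L) {
    # decoy-free screen: the baseline ratio is undefined; report the
    # sentinel directly rather than a spurious number
    counts <- list(active_hits = a_hit, decoy_hits = 0L,
                   actives_total = a_tot, decoys_total = 0L)
    ef <- if (a_hit > 0) list(ef = Inf, flag = "no-decoy-hits")
          else list(ef = NA_real_, flag = "NA")
  } else {
    counts <- screen_counts(a_hit, d_hit, a_tot, d_tot)
    ef <- enrichment_factor(counts)
  }
  list(counts = counts, ef = ef$ef, flag = ef$flag,
       active_hits = rk$molecule_id[rk$matched & rk$activity == "active"],
       decoy_hits = rk$molecule_id[rk$matched & rk$activity == "decoy"],
       unknown = r$molecule_id[!known])
}
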