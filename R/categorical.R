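#' Descriptor vocabulary for percept reports
#'
#' Descriptors a subject can select when characterizing an evoked sensation,
#' grouped by modality category. `pins_needles` abbreviates pins-and-needles,
#' `across_skin` movement across the skin, `body_limb_joint` movement of a
#' body part, limb, or joint.
#'
#' @return Named list of character vectors (`mechanical`, `tingle`,
#'   `movement`, `temperature`).
#' @export
descriptor_vocabulary <- function() {
  list(mechanical = c("touch", "pressure", "sharp"),
       tingle = c("electrical", "tickle", "itch", "pins_needles"),
       movement = c("vibration", "across_skin", "body_limb_joint"),
       temperature = "temperature")
}

#' Paresthetic descriptor set
#'
#' Sensations carrying an electrical-tingle, pins-and-needles, sharp, or
#' tickle component are considered paresthetic. Note the set is defined by
#' the classification rule, not by the vocabulary's column layout ('sharp'
#' sits in the mechanical column but is paresthetic; 'itch' sits in the
#' tingle column but is not, unless `include_itch`).
#'
#' @param include_itch Also count `itch` as paresthetic (default `FALSE`).
#' @export
paresthetic_descriptors <- function(include_itch = FALSE) {
  base <- c("electrical", "pins_needles", "sharp", "tickle")
  if (include_itch) c(base, "itch") else base
}

#' Classify the modality of a percept report
#'
#' A report containing only paresthetic descriptors is `paresthetic`; one
#' containing paresthetic plus any mechanical/movement/temperature descriptor
#' is `mixed`; one with no paresthetic descriptor is `naturalistic`. The
#' three classes partition every non-empty report.
#'
#' @param descriptors Character vector of descriptor tokens from
#'   [descriptor_vocabulary()] (a single report), or a list of such vectors.
#' @param include_itch Treat `itch` as paresthetic.
#' @return Character: `"paresthetic"`, `"mixed"`, or `"naturalistic"` (one
#'   per report).
#' @examples
#' classify_modality(c("pressure", "electrical")) # "mixed"
#' @export
classify_modality <- function(descriptors, include_itch = FALSE) {
  if (is.list(descriptors))
    return(vapply(descriptors, classify_modality, character(1),
                  include_itch = include_itch))
  vocab <- unlist(descriptor_vocabulary(), use.names = FALSE)
  if (length(descriptors) == 0) abort("report has no descriptors.")
  unknown <- setdiff(descriptors, vocab)
  if (length(unknown))
    abort(paste0("unknown descriptor token(s): ",
                 paste(unknown, collapse = ", ")))
  par_set <- paresthetic_descriptors(include_itch)
  has_par <- any(descriptors %in% par_set)
  has_other <- any(!descriptors %in% par_set)
  if (!has_par) "naturalistic" else if (has_other) "mixed" else "paresthetic"
}

#' Modality summary over a set of reports
#'
#' @param reports List of descriptor vectors, or a data frame with logical/0-1
#'   descriptor columns (one row per report).
#' @param include_itch Treat `itch` as paresthetic.
#' @return Tibble: `modality`, `n`, `fraction` (fractions over all reports).
#' @export
modality_fractions <- function(reports, include_itch = FALSE) {
  reports <- as_report_list(reports)
  cls <- classify_modality(reports, include_itch = include_itch)
  tibble::tibble(modality = c("paresthetic", "mixed", "naturalistic")) |>
    dplyr::mutate(n = vapply(.data$modality, function(m) sum(cls == m),
                             integer(1), USE.NAMES = FALSE),
                  fraction = .data$n / length(cls))
}

# Accept either a list of token vectors or a wide 0/1 data frame.
as_report_list <- function(reports) {
  if (is.data.frame(reports)) {
    vocab <- unlist(descriptor_vocabulary(), use.names = FALSE)
    cols <- intersect(names(reports), vocab)
    if (!length(cols)) abort("no descriptor columns found in report table.")
    lapply(seq_len(nrow(reports)), function(i)
      cols[as.logical(unlist(reports[i, cols]))])
  } else if (is.list(reports)) reports
  else abort("`reports` must be a list of descriptor vectors or a data frame.")
}

#' Hierarchical descriptor counts for a sunburst chart
#'
#' Counts reports along the tingle -> mechanical -> movement hierarchy: the
#' inner level counts each tingle descriptor (plus `"(none)"` for reports
#' without one), the middle level each mechanical descriptor co-occurring
#' within its parent, and the outer level each movement descriptor within
#' that. Child counts never exceed their parent's.
#'
#' @param reports As in [modality_fractions()].
#' @return Tibble: `level` (1–3), `tingle`, `mechanical`, `movement`, `n`
#'   (`NA` for levels not applicable to a row); zero-count paths are omitted.
#' @export
sunburst_counts <- function(reports) {
  reports <- as_report_list(reports)
  vocab <- descriptor_vocabulary()
  rows <- list()
  tingle_opts <- c(vocab$tingle, "(none)")
  for (tg in tingle_opts) {
    in_t <- if (tg == "(none)")
      vapply(reports, function(r) !any(r %in% vocab$tingle), logical(1))
    else vapply(reports, function(r) tg %in% r, logical(1))
    if (!any(in_t)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      level = 1L, tingle = tg, mechanical = NA_character_,
      movement = NA_character_, n = sum(in_t))
    sub_t <- reports[in_t]
    for (mech in vocab$mechanical) {
      in_m <- vapply(sub_t, function(r) mech %in% r, logical(1))
      if (!any(in_m)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        level = 2L, tingle = tg, mechanical = mech,
        movement = NA_character_, n = sum(in_m))
      sub_m <- sub_t[in_m]
      for (mov in vocab$movement) {
        n3 <- sum(vapply(sub_m, function(r) mov %in% r, logical(1)))
        if (n3 == 0) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          level = 3L, tingle = tg, mechanical = mech, movement = mov, n = n3)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Assign a percept mask to a body region
#'
#' The region whose intersection with the mask has the maximal pixel area;
#' exact ties are broken deterministically by the fixed distal-first region
#' order ([arm_regions]).
#'
#' @param mask A `percept_mask`.
#' @return Region label (character), or `NA` with a warning if the mask lies
#'   entirely outside the labeled regions.
#' @export
assign_body_region <- function(mask) {
  stopifnot(inherits(mask, "percept_mask"))
  labs <- mask$template$labels[mask$pixels]
  labs <- labs[labs > 0L]
  if (!length(labs)) {
    warn("mask lies entirely outside labeled regions; unassigned.")
    return(NA_character_)
  }
  counts <- tabulate(labs, nbins = length(mask$template$regions))
  mask$template$regions[which.max(counts)]  # which.max: first (distal) wins ties
}

#' Dermatome proportion matrix
#'
#' For each anatomical region, the distribution over spinal levels of the
#' electrodes that evoked a sensation there. Only ipsilateral percepts enter;
#' electrodes that evoked exclusively bilateral or contralateral sensations
#' are excluded, as are electrodes without a spinal level (logged via
#' warning). Columns over represented levels sum to 1; regions never evoked
#' are all-`NA` columns (distinguishable from structural zeros).
#'
#' @param electrodes Data frame: `electrode`, `spinal_level`.
#' @param percepts Data frame: `electrode`, `region`, and optionally
#'   `laterality` (rows not `"ipsilateral"` are dropped).
#' @param regions Region vocabulary defining the column order.
#' @return Tibble with `spinal_level` and one proportion column per region.
#' @export
dermatome_proportions <- function(electrodes, percepts,
                                  regions = arm_regions) {
  stopifnot(all(c("electrode", "spinal_level") %in% names(electrodes)))
  stopifnot(all(c("electrode", "region") %in% names(percepts)))
  if ("laterality" %in% names(percepts))
    percepts <- dplyr::filter(percepts, .data$laterality == "ipsilateral")
  missing_lvl <- electrodes$electrode[is.na(electrodes$spinal_level)]
  if (length(missing_lvl))
    warn(paste0("electrodes without spinal level excluded: ",
                paste(missing_lvl, collapse = ", ")))
  electrodes <- dplyr::filter(electrodes, !is.na(.data$spinal_level))
  joined <- percepts |>
    dplyr::inner_join(electrodes, by = "electrode") |>
    dplyr::distinct(.data$electrode, .data$spinal_level, .data$region)
  levels_all <- sort(unique(electrodes$spinal_level))
  out <- tibble::tibble(spinal_level = levels_all)
  for (rg in regions) {
    sub <- dplyr::filter(joined, .data$region == rg)
    if (nrow(sub) == 0) {
      out[[rg]] <- NA_real_
    } else {
      cnt <- table(factor(sub$spinal_level, levels = levels_all))
      out[[rg]] <- as.numeric(cnt) / sum(cnt)
    }
  }
  out
}
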