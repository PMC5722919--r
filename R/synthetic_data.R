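# Synthetic event tables with known ground truth, plus the published
# 94-event table skeleton (names, regions, class labels) as a fixture.

#' Configuration for a synthetic event table
#'
#' Describes the generating model the analysis assumes: each region belongs
#' wholly to one latent group; its events draw human timings uniformly from
#' `pcw_range` and rat timings from the group's line plus Gaussian noise.
#'
#' @param regions Data.frame with columns `label`, `group` (integer index
#'   into `groups`) and `n_events` (>= 1).
#' @param groups Data.frame with columns `slope`, `intercept`, `sigma`
#'   (>= 0) and optionally `label`.
#' @param pcw_range Length-2 human timing range in pcw (default `[5, 38]`,
#'   the foetal span the event data cover).
#' @param seed Default seed for [generate_dataset()].
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(regions, groups, pcw_range = c(5, 38), seed = 1) {
  stopifnot(all(c("label", "group", "n_events") %in% names(regions)),
            all(c("slope", "intercept", "sigma") %in% names(groups)))
  if (any(regions$n_events < 1)) {
    abort("event counts must be >= 1", "devtrans_validation_error")
  }
  if (any(groups$sigma < 0)) {
    abort("sigmas must be >= 0", "devtrans_validation_error")
  }
  if (any(regions$group < 1 | regions$group > nrow(groups))) {
    abort("every region's true group must index into groups",
          "devtrans_validation_error")
  }
  if (anyDuplicated(regions$label)) {
    abort("duplicate region labels", "devtrans_validation_error")
  }
  structure(
    list(regions = as.data.frame(regions), groups = as.data.frame(groups),
         true_K = nrow(groups), pcw_range = pcw_range, seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a synthetic event table with its ground truth
#'
#' @param config A [synthetic_config()].
#' @param seed Seed override (default `config$seed`). Same seed, same table.
#' @return List with `table` (a valid [event_table()], event ids sequential
#'   in region order) and `truth` (region assignments, true group
#'   parameters, the config and seed) for recovery scoring.
#' @examples
#' out <- generate_dataset(study_design_config())
#' nrow(out$table)
#' @export
generate_dataset <- function(config, seed = config$seed) {
  if (!inherits(config, "synthetic_config")) {
    abort("config must be a synthetic_config", "devtrans_validation_error")
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(config$regions)), function(r) {
      n <- config$regions$n_events[r]
      g <- config$regions$group[r]
      pcw <- stats::runif(n, config$pcw_range[1], config$pcw_range[2])
      pcd <- config$groups$slope[g] * pcw + config$groups$intercept[g] +
        stats::rnorm(n, 0, config$groups$sigma[g])
      data.frame(name = sprintf("synthetic event (%s)", config$regions$label[r]),
                 region = config$regions$label[r],
                 human_pcw = pcw, rat_pcd = pcd,
                 mouse_derived = FALSE, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$event_id <- seq_len(nrow(df))
    tab <- event_table(df)
    truth <- list(
      assignments = stats::setNames(config$regions$group, config$regions$label),
      groups = config$groups, config = config, seed = seed
    )
    list(table = tab, truth = truth)
  })
}

#' The published 94-event table skeleton
#'
#' Event names, brain regions and the published two- and four-class
#' clustering labels of the 94 comparative developmental events. The four-
#' class labels exist only for events 1-79 (the clustering subset); event
#' 94 (birth) carries no class. Timing columns are absent unless a
#' transcribed timing CSV (`event_id,human_pcw,rat_pcd`) is joined on
#' `event_id`, in which case a full [event_table()] is returned.
#'
#' @param timings_csv Optional path to a CSV with columns
#'   `event_id,human_pcw,rat_pcd` transcribed from the published
#'   supplementary data (not redistributed with the package).
#' @return Without timings: data.frame `event_id,name,region,class2,class4`.
#'   With timings: an [event_table()] carrying `class2`/`class4` as extra
#'   attributes `"classes"`.
#' @export
table1_fixture <- function(timings_csv = NULL) {
  path <- system.file("extdata", "table1_events.csv", package = "devtrans")
  fix <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("integer", "character", "character",
                                        "character", "character"))
  fix$class2[!nzchar(fix$class2)] <- NA_character_
  fix$class4[!nzchar(fix$class4)] <- NA_character_
  if (is.null(timings_csv)) return(fix)
  tim <- utils::read.csv(timings_csv, stringsAsFactors = FALSE)
  need <- c("event_id", "human_pcw", "rat_pcd")
  if (!all(need %in% names(tim))) {
    abort("timings CSV must have columns event_id,human_pcw,rat_pcd",
          "devtrans_format_error")
  }
  orphans <- setdiff(tim$event_id, fix$event_id)
  missing <- setdiff(fix$event_id, tim$event_id)
  if (length(orphans) > 0 || length(missing) > 0) {
    abort(sprintf(
      "timing join mismatch; ids not in fixture: %s; fixture ids without timing: %s",
      paste(orphans, collapse = ", "), paste(missing, collapse = ", ")),
      "devtrans_integrity_error")
  }
  m <- match(fix$event_id, tim$event_id)
  tab <- event_table(data.frame(
    event_id = fix$event_id, name = fix$name, region = fix$region,
    human_pcw = tim$human_pcw[m], rat_pcd = tim$rat_pcd[m],
    mouse_derived = FALSE, stringsAsFactors = FALSE))
  attr(tab, "classes") <- fix[, c("event_id", "class2", "class4")]
  tab
}

#' Region tallies of the published event table
#'
#' Counts events per named brain region, with an `"others"` bucket for the
#' non-neural rows (the generic "Other N" entries and the skeletal
#' ossification events); the vomeronasal organ and optic nerve count as
#' their own regions.
#'
#' @param fixture Output of [table1_fixture()] (defaults to the shipped
#'   skeleton).
#' @return Named integer vector of counts.
#' @export
region_tally <- function(fixture = table1_fixture()) {
  named <- c("Spinal cord", "DRG", "Medulla/pons", "Cerebellum", "Midbrain",
             "Thalamus", "Hypothalamus", "Subcortex", "Allocortex",
             "Isocortex", "Retina")
  other <- grepl("^Other ", fixture$region) | fixture$region == "Skeleton"
  counts <- vapply(named, function(r) sum(fixture$region == r), integer(1))
  c(counts, others = sum(other),
    vapply(setdiff(unique(fixture$region), c(named, fixture$region[other])),
           function(r) sum(fixture$region == r), integer(1)))
}

#' Synthetic configuration mirroring the published study design
#'
#' Region labels and event counts copy the published 94-event table; each
#' region's true group copies the published two-class assignment, and the
#' two generating lines are the final two-group equations
#' (`1.258 x + 6.832` and `0.774 x + 7.417`) with a common residual SD of
#' 2.4 pcd (the reported model RMSE). The birth-date region ("Other 10")
#' has no published class — it was excluded from the analysis — and is
#' arbitrarily completed as the slow group.
#'
#' @param sigma Residual SD in pcd for both groups.
#' @param pcw_range Human timing range.
#' @param seed Default generation seed.
#' @return A [synthetic_config()].
#' @export
study_design_config <- function(sigma = 2.4, pcw_range = c(5, 38), seed = 1) {
  fix <- table1_fixture()
  fix$class2[fix$region == "Other 10"] <- "B2"
  reg_labels <- unique(fix$region)
  regions <- data.frame(
    label = reg_labels,
    group = ifelse(fix$class2[match(reg_labels, fix$region)] == "A2", 1L, 2L),
    n_events = vapply(reg_labels, function(r) sum(fix$region == r), integer(1)),
    stringsAsFactors = FALSE
  )
  groups <- data.frame(
    label = c("A2", "B2"),
    slope = c(1.258, 0.774),
    intercept = c(6.832, 7.417),
    sigma = sigma
  )
  synthetic_config(regions, groups, pcw_range = pcw_range, seed = seed)
}
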