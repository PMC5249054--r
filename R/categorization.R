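#' Morphology classification rules
#'
#' Thresholds of the rule scheme mapping per-sample SMI statistics and
#' equivalent diameters to mammography-analog morphology categories:
#'
#' * fine linear (`fl`): mean cube-equivalent diameter `< 200` um AND
#'   mean SMI inside the closed interval `[2.92, 3.08]` (rod-like);
#' * fine pleomorphic (`fp`): mean cube-equivalent diameter `< 250` um
#'   AND SD of the SMI strictly `> 0.29` (heterogeneous shapes);
#' * coarse heterogeneous (`ch`): largest sphere-equivalent diameter
#'   `> 500` um AND SD of the SMI strictly `> 0.5`;
#' * not suspicious (`ns`): none of the above.
#'
#' The boundary conventions (strict size bounds, inclusive SMI interval,
#' strict SD bounds) are pinned by the reference cohort: a sample with
#' SD exactly 0.29 is `ns`, a sample with mean SMI exactly 3.08 is `fl`.
#' The `ch` size predicate uses the largest object because a single big
#' calcification drives that category while sample means stay far below
#' 500 um.
#'
#' @param fl_max_d_cube,fp_max_d_cube um, strict upper bounds.
#' @param fl_smi_range Closed interval for the mean SMI.
#' @param fp_min_sd_smi,ch_min_sd_smi Strict lower bounds on SD(SMI).
#' @param ch_min_d um, strict lower bound on the largest
#'   sphere-equivalent diameter.
#' @return A `classification_rules` list.
#' @export
classification_rules <- function(fl_max_d_cube = 200,
                                 fl_smi_range = c(2.92, 3.08),
                                 fp_max_d_cube = 250,
                                 fp_min_sd_smi = 0.29,
                                 ch_min_d = 500,
                                 ch_min_sd_smi = 0.5) {
  stopifnot(length(fl_smi_range) == 2L,
            fl_smi_range[1] <= fl_smi_range[2],
            fl_max_d_cube < fp_max_d_cube, fp_max_d_cube < ch_min_d)
  structure(list(fl_max_d_cube = fl_max_d_cube,
                 fl_smi_range = fl_smi_range,
                 fp_max_d_cube = fp_max_d_cube,
                 fp_min_sd_smi = fp_min_sd_smi,
                 ch_min_d = ch_min_d,
                 ch_min_sd_smi = ch_min_sd_smi),
            class = "classification_rules")
}

#' Assign morphology flags to a sample
#'
#' Applies the rule scheme of [classification_rules()] to a per-sample
#' aggregate. The three suspicious flags are evaluated independently
#' (a sample may be both `fl` and `fp`); `ns` is their joint negation.
#' Samples flagged `excluded` (single calcification) are refused.
#'
#' @param sample One-row data.frame from [aggregate_sample()] (needs
#'   `mean_SMI`, `sd_SMI`, `mean_d_cube_um`, `max_d_sphere_um`,
#'   `excluded`).
#' @param rules A [classification_rules()].
#' @return One-row data.frame with logical columns `fl`, `fp`, `ch`, `ns`.
#' @export
classify_sample <- function(sample, rules = classification_rules()) {
  stopifnot(nrow(sample) == 1L)
  if (isTRUE(sample$excluded))
    stop("sample ", sample$sample_id, " is excluded from categorization ",
         "(a single microcalcification is non-representative)")
  if (sample$n_objects < 1L) stop("sample has no objects")
  fl <- sample$mean_d_cube_um < rules$fl_max_d_cube &&
    sample$mean_SMI >= rules$fl_smi_range[1] &&
    sample$mean_SMI <= rules$fl_smi_range[2]
  fp <- sample$mean_d_cube_um < rules$fp_max_d_cube &&
    sample$sd_SMI > rules$fp_min_sd_smi
  ch <- !is.na(sample$max_d_sphere_um) &&
    sample$max_d_sphere_um > rules$ch_min_d &&
    sample$sd_SMI > rules$ch_min_sd_smi
  data.frame(fl = fl, fp = fp, ch = ch, ns = !(fl || fp || ch))
}

#' Assign morphology flags to a single object
#'
#' Secondary per-object mode: the size and SMI predicates are evaluated
#' on the object's own `d_cube` and `SMI`. The `fp` and `ch` predicates
#' involve the SD of the SMI, which only exists across a sample's
#' objects; per object they are undefined and always `FALSE` — this mode
#' can therefore only produce `fl` or `ns`.
#'
#' @param obj One-row data.frame from [measure_objects()].
#' @param rules A [classification_rules()].
#' @return One-row data.frame with `fl`, `fp`, `ch`, `ns`.
#' @export
classify_object <- function(obj, rules = classification_rules()) {
  stopifnot(nrow(obj) == 1L)
  fl <- obj$d_cube_um < rules$fl_max_d_cube &&
    obj$SMI >= rules$fl_smi_range[1] && obj$SMI <= rules$fl_smi_range[2]
  data.frame(fl = fl, fp = FALSE, ch = FALSE, ns = !fl)
}

#' Map a histopathology B-classification to group A/B/C
#'
#' Group A collects normal and benign findings (B1, B2), group B lesions
#' of uncertain malignant potential or suspicious of malignancy (B3, B4)
#' and group C malignant lesions (B5).
#'
#' @param b_class Character vector of categories `"B1"`..`"B5"`.
#' @return Factor with levels `A`, `B`, `C`.
#' @export
assign_group <- function(b_class) {
  map <- c(B1 = "A", B2 = "A", B3 = "B", B4 = "B", B5 = "C")
  bad <- setdiff(unique(b_class), names(map))
  if (length(bad))
    stop("unknown B-classification: ", paste(bad, collapse = ", "))
  factor(unname(map[b_class]), levels = c("A", "B", "C"))
}

#' Presence/absence contingency table of a morphology flag by group
#'
#' Counts, per histologic group, the samples carrying vs not carrying a
#' flag. Excluded samples must be removed beforehand.
#'
#' @param records Data.frame with a `group` column (levels A/B/C) and a
#'   logical/0-1 column named by `flag`.
#' @param flag One of `"fl"`, `"fp"`, `"ch"`, `"ns"`.
#' @return 2 x 3 integer matrix, rows `present`/`absent`, columns
#'   `A`/`B`/`C`.
#' @export
presence_table <- function(records, flag = c("fl", "fp", "ch", "ns")) {
  flag <- match.arg(flag)
  grp <- factor(records$group, levels = c("A", "B", "C"))
  if (any(table(grp) == 0L))
    stop("empty group: ",
         paste(levels(grp)[table(grp) == 0L], collapse = ", "))
  present <- as.logical(records[[flag]])
  tab <- rbind(present = tapply(present, grp, sum),
               absent = tapply(!present, grp, sum))
  storage.mode(tab) <- "integer"
  tab
}
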