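## Region atlases: region_id (0-based, external convention), name, hemisphere,
## homolog_id (shared by the two members of a bilateral pair, NA otherwise),
## cortical flag. Row order is the canonical region order for every matrix and
## vector in the package; internal code indexes rows 1-based.

aal_base_names <- c(
  "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
  "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri", "Frontal_Inf_Orb",
  "Rolandic_Oper", "Supp_Motor_Area", "Olfactory", "Frontal_Sup_Medial",
  "Frontal_Med_Orb", "Rectus", "Insula", "Cingulum_Ant", "Cingulum_Mid",
  "Cingulum_Post", "Hippocampus", "ParaHippocampal", "Amygdala", "Calcarine",
  "Cuneus", "Lingual", "Occipital_Sup", "Occipital_Mid", "Occipital_Inf",
  "Fusiform", "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
  "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
  "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
  "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")

aal_cerebellum_names <- c(
  paste0(rep(c("Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3",
               "Cerebelum_4_5", "Cerebelum_6", "Cerebelum_7b", "Cerebelum_8",
               "Cerebelum_9", "Cerebelum_10"), each = 2), c("_L", "_R")),
  paste0("Vermis_", c("1_2", "3", "4_5", "6", "7", "8", "9", "10")))

#' Default 116-region anatomical atlas
#'
#' The standard anatomical-labeling parcellation: 90 cerebral regions as 45
#' interleaved left/right homolog pairs (regions 1-90, `Precentral_L`,
#' `Precentral_R`, ...), followed by 26 cerebellar regions (18 hemispheric, 8
#' vermis). Only the 45 cerebral pairs carry a `homolog_id`; cerebellar
#' regions are excluded from the asymmetry pair set.
#'
#' @return a `region_atlas` data.frame with columns `region_id` (0-based),
#'   `name`, `hemisphere` (`left`/`right`/`midline`), `homolog_id` (integer or
#'   NA), `cortical` (logical).
#' @examples
#' a <- aal_atlas()
#' sum(a$cortical)                      # 90
#' length(unique(na.omit(a$homolog_id)))  # 45
#' @export
aal_atlas <- function() {
  cortex <- data.frame(
    region_id = 0:89,
    name = paste0(rep(aal_base_names, each = 2), c("_L", "_R")),
    hemisphere = rep(c("left", "right"), 45),
    homolog_id = rep(seq_len(45), each = 2),
    cortical = TRUE)
  cb_hemi <- grepl("_[LR]$", aal_cerebellum_names)
  cereb <- data.frame(
    region_id = 90:115,
    name = aal_cerebellum_names,
    hemisphere = ifelse(!cb_hemi, "midline",
                        ifelse(grepl("_L$", aal_cerebellum_names), "left", "right")),
    homolog_id = NA_integer_,
    cortical = FALSE)
  new_atlas(rbind(cortex, cereb))
}

#' Synthetic atlas for small test cohorts
#'
#' Builds a reduced atlas with `n_pairs` left/right cortical homolog pairs
#' (interleaved, mirroring the default atlas layout) and `n_extra` unpaired
#' non-cortical regions appended at the end.
#'
#' @param n_pairs number of bilateral cortical pairs.
#' @param n_extra number of unpaired non-cortical regions.
#' @return a `region_atlas`.
#' @export
synthetic_atlas <- function(n_pairs, n_extra = 0) {
  stopifnot(n_pairs >= 1, n_extra >= 0)
  cortex <- data.frame(
    region_id = seq_len(2 * n_pairs) - 1L,
    name = paste0("Region_", rep(seq_len(n_pairs), each = 2), c("_L", "_R")),
    hemisphere = rep(c("left", "right"), n_pairs),
    homolog_id = rep(seq_len(n_pairs), each = 2),
    cortical = TRUE)
  out <- cortex
  if (n_extra > 0) {
    out <- rbind(cortex, data.frame(
      region_id = 2 * n_pairs + seq_len(n_extra) - 1L,
      name = paste0("Extra_", seq_len(n_extra)),
      hemisphere = "midline",
      homolog_id = NA_integer_,
      cortical = FALSE))
  }
  new_atlas(out)
}

new_atlas <- function(df) {
  validate_atlas(df)
  class(df) <- c("region_atlas", "data.frame")
  df
}

validate_atlas <- function(df) {
  need <- c("region_id", "name", "hemisphere", "homolog_id", "cortical")
  if (!all(need %in% names(df)))
    stop("atlas must have columns: ", paste(need, collapse = ", "))
  if (!identical(as.integer(df$region_id), seq_len(nrow(df)) - 1L))
    stop("atlas region_ids must be contiguous 0..P-1 in row order")
  if (anyDuplicated(df$name)) stop("duplicate region names in atlas")
  if (!all(df$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be left/right/midline")
  hid <- df$homolog_id[!is.na(df$homolog_id)]
  if (length(hid)) {
    tab <- table(hid)
    if (any(tab != 2)) stop("every homolog_id must be shared by exactly two regions")
    for (h in unique(hid)) {
      hs <- df$hemisphere[!is.na(df$homolog_id) & df$homolog_id == h]
      if (!setequal(hs, c("left", "right")))
        stop("homolog_id ", h, " must pair one left and one right region")
    }
  }
  invisible(df)
}

#' Read / write an atlas TSV
#'
#' Tab-separated with header columns `region_id`, `name`, `hemisphere`,
#' `homolog_id`, `cortical`; missing homolog_id written as `NA`.
#'
#' @param path file path.
#' @return `read_atlas()` returns a validated `region_atlas`.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$homolog_id <- suppressWarnings(as.integer(df$homolog_id))
  df$cortical <- as.logical(df$cortical)
  new_atlas(df)
}

#' @rdname read_atlas
#' @param atlas a `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Homolog pair table
#'
#' @param atlas a `region_atlas`.
#' @return data.frame with one row per bilateral pair, ordered by
#'   `homolog_id`: columns `homolog_id`, `left`, `right` (1-based row indices
#'   into the atlas), `name` (base name of the left member).
#' @export
homolog_pairs <- function(atlas) {
  hid <- sort(unique(atlas$homolog_id[!is.na(atlas$homolog_id)]))
  left <- right <- integer(length(hid))
  for (q in seq_along(hid)) {
    rows <- which(!is.na(atlas$homolog_id) & atlas$homolog_id == hid[q])
    left[q] <- rows[atlas$hemisphere[rows] == "left"]
    right[q] <- rows[atlas$hemisphere[rows] == "right"]
  }
  data.frame(homolog_id = hid, left = left, right = right,
             name = sub("_L$", "", atlas$name[left]))
}

## Map each cortical region's 1-based index to its partner's index.
homolog_partner <- function(atlas) {
  pairs <- homolog_pairs(atlas)
  partner <- rep(NA_integer_, nrow(atlas))
  partner[pairs$left] <- pairs$right
  partner[pairs$right] <- pairs$left
  partner
}
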