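#' Classification thresholds and name patterns
#'
#' The published module names (neurocranial, left/right/main facial,
#' suprahyoid and tongue, laryngeal movement, true vocal fold movement,
#' postcranial) are verbal; this package makes them operational with a rule
#' set driven by composition fractions and anatomical name patterns. All
#' thresholds are exposed here so the approximation is tunable.
#'
#' @param facial_fraction Minimum fraction of module nodes that are
#'   facial-expression muscles or facial bones for a `*_facial` label.
#' @param main_facial_min_side A facial module is `main_facial` when each
#'   body side holds at least this fraction of its sided nodes.
#' @param dominance Minimum fraction of module nodes matching a class
#'   signature for the non-facial labels.
#' @param facial_bone_pattern,arytenoid_pattern,laryngeal_pattern,
#'   suprahyoid_pattern,postcranial_pattern,neurocranial_pattern Regular
#'   expressions applied to node names (case-insensitive).
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(facial_fraction = 0.5,
                            main_facial_min_side = 0.25,
                            dominance = 0.5,
                            facial_bone_pattern =
                              "maxilla|zygomatic|nasal|lacrimal|palatine|vomer|jugal|incisive",
                            arytenoid_pattern = "arytenoid|vocalis",
                            laryngeal_pattern =
                              "cricoid|thyroid|cricothyro|crico|thyro|laryn",
                            suprahyoid_pattern =
                              "hyoid|hyo|tongue|gloss|genio|mylo|digastric",
                            postcranial_pattern =
                              "vertebra|atlas|axis|clavicle|scapula|sternum|rib|trapezius|sternocleido",
                            neurocranial_pattern =
                              "frontal|parietal|occipital|temporal|sphenoid|ethmoid|squamosal|petrosal|basi|cranium|neurocran") {
  structure(as.list(environment()), class = "classify_config")
}

#' Recognized module class labels
#' @return Character vector of labels assignable by [profile_module()].
#' @export
module_labels <- function() {
  c("neurocranial", "left_facial", "right_facial", "main_facial",
    "suprahyoid_tongue", "laryngeal_movement", "true_vocal_fold_movement",
    "laryngeal_and_vocal_fold", "postcranial", "other")
}

#' Composition profile and class label of one module
#'
#' Tallies tissue, body side and facial-expression counts for the nodes of
#' one module and assigns an anatomical class label. The rules, in order:
#'
#' 1. *facial* if at least `facial_fraction` of nodes are facial-expression
#'    muscles or facial bones (by name pattern); sub-label `main_facial`
#'    when both sides are well represented among sided nodes, else
#'    `left_facial`/`right_facial` by majority side. A one-sided facial
#'    module is `asymmetric` when it contains any node of the opposite side
#'    — the hallmark of the anthropoid pattern, where asymmetry lies in the
#'    network modules rather than in the muscles themselves.
#' 2. `true_vocal_fold_movement` if every node is arytenoid-associated
#'    (arytenoid cartilages and the muscles acting on them);
#'    `laryngeal_and_vocal_fold` when larynx-associated names dominate and
#'    both arytenoid and cricoid/thyroid structures are present;
#'    `laryngeal_movement` when cricoid/thyroid structures dominate.
#' 3. `suprahyoid_tongue`, `postcranial`, `neurocranial` by dominant name
#'    pattern (plus the hypobranchial muscle group for the tongue module).
#' 4. `other` when nothing dominates.
#'
#' @param net An [anatomical_network()].
#' @param partition An `anna_partition` (or named module-id vector).
#' @param module_id Module id present in the partition.
#' @param metadata Optional metadata; defaults to the network's own.
#' @param config A [classify_config()].
#' @return An object of class `module_profile`: list with `module_id`,
#'   `size`, `members`, `tissue_counts`, `side_counts`,
#'   `facial_muscle_count`, `label`, `asymmetric`.
#' @export
profile_module <- function(net, partition, module_id, metadata = NULL,
                           config = classify_config()) {
  p <- partition_vector(partition)
  if (!module_id %in% p) stop("unknown module id: ", module_id)
  meta <- if (is.null(metadata)) net$meta else validate_metadata(metadata)
  members <- names(p)[p == module_id]
  miss <- setdiff(members, meta$node)
  if (length(miss) > 0)
    stop("metadata missing for node(s): ", paste(miss, collapse = ", "))
  mm <- meta[match(members, meta$node), , drop = FALSE]
  voc <- meta_vocabulary()

  tissue_counts <- vapply(voc$tissue, function(t) sum(mm$tissue == t), integer(1))
  side_counts <- vapply(voc$side, function(s) sum(mm$side == s), integer(1))
  facial_n <- sum(mm$is_facial_expression)
  size <- length(members)
  nm <- tolower(members)

  is_facial_bone <- mm$tissue %in% c("bone", "cartilage") &
    grepl(config$facial_bone_pattern, nm, ignore.case = TRUE)
  facial_like <- (facial_n + sum(is_facial_bone)) / size

  is_aryt <- grepl(config$arytenoid_pattern, nm, ignore.case = TRUE)
  is_laryn <- grepl(config$laryngeal_pattern, nm, ignore.case = TRUE)
  is_supra <- grepl(config$suprahyoid_pattern, nm, ignore.case = TRUE) |
    mm$group == "hypobranchial"
  is_post <- grepl(config$postcranial_pattern, nm, ignore.case = TRUE)
  is_neuro <- grepl(config$neurocranial_pattern, nm, ignore.case = TRUE)

  label <- "other"
  asymmetric <- FALSE
  sided <- side_counts[["left"]] + side_counts[["right"]]
  if (facial_like >= config$facial_fraction) {
    if (sided > 0 &&
        min(side_counts[["left"]], side_counts[["right"]]) / sided >=
        config$main_facial_min_side) {
      label <- "main_facial"
    } else if (side_counts[["left"]] >= side_counts[["right"]]) {
      label <- "left_facial"
      asymmetric <- side_counts[["right"]] > 0
    } else {
      label <- "right_facial"
      asymmetric <- side_counts[["left"]] > 0
    }
  } else if (all(is_aryt)) {
    label <- "true_vocal_fold_movement"
  } else if (mean(is_aryt | is_laryn) >= config$dominance &&
             any(is_aryt) && any(is_laryn & !is_aryt)) {
    label <- "laryngeal_and_vocal_fold"
  } else if (mean(is_laryn) >= config$dominance) {
    label <- "laryngeal_movement"
  } else if (mean(is_supra) >= config$dominance) {
    label <- "suprahyoid_tongue"
  } else if (mean(is_post) >= config$dominance) {
    label <- "postcranial"
  } else if (mean(is_neuro) >= config$dominance) {
    label <- "neurocranial"
  }

  structure(list(module_id = module_id, size = size, members = members,
                 tissue_counts = tissue_counts, side_counts = side_counts,
                 facial_muscle_count = as.integer(facial_n),
                 label = label, asymmetric = asymmetric),
            class = "module_profile")
}

#' @export
print.module_profile <- function(x, ...) {
  cat(sprintf("module %s [%s]: %d node(s), %d facial muscle(s)%s\n",
              x$module_id, x$label, x$size, x$facial_muscle_count,
              if (x$asymmetric) ", asymmetric" else ""))
  invisible(x)
}

#' Profile every module of a partition
#'
#' @inheritParams profile_module
#' @return A list of `module_profile` objects, one per module id.
#' @export
profile_modules <- function(net, partition, metadata = NULL,
                            config = classify_config()) {
  ids <- sort(unique(partition_vector(partition)))
  lapply(ids, function(id)
    profile_module(net, partition, id, metadata = metadata, config = config))
}

# round half away from zero; R's round() halves to even
round_half_up <- function(x) floor(x + 0.5)

#' Facial-muscle inclusion percentage from raw counts
#'
#' `100 * n_in / n_total`, rounded half-up to an integer as conventionally
#' printed (e.g. 36 of 48 facial-expression muscles inside facial modules
#' gives 75).
#'
#' @param n_in Facial-expression muscles inside facial-labeled modules.
#' @param n_total All facial-expression muscles in the network.
#' @return Integer percentage in `[0, 100]`.
#' @export
#' @examples
#' facial_inclusion_percent(36, 48)  # 75
#' facial_inclusion_percent(29, 44)  # 66
facial_inclusion_percent <- function(n_in, n_total) {
  if (n_total < 1) stop("no facial-expression muscles in metadata")
  if (n_in > n_total) stop("n_in exceeds n_total")
  as.integer(round_half_up(100 * n_in / n_total))
}

#' Facial-muscle inclusion of a partition
#'
#' Fraction of facial-expression muscles that fall inside modules labeled
#' `left_facial`, `right_facial` or `main_facial`. Left and right muscle
#' instances count as separate nodes, consistent with published denominators
#' that differ by taxon.
#'
#' @param partition An `anna_partition` or named module-id vector.
#' @param metadata Metadata data frame marking facial-expression muscles.
#' @param profiles Labeled profiles from [profile_modules()].
#' @param taxon_id Taxon label for the report row.
#' @return A list of class `facial_inclusion` with `taxon_id`, `n_in_facial`,
#'   `n_total_facial`, `percent`.
#' @export
facial_inclusion <- function(partition, metadata, profiles,
                             taxon_id = "unnamed_taxon") {
  p <- partition_vector(partition)
  meta <- validate_metadata(metadata)
  facial_nodes <- meta$node[meta$is_facial_expression]
  n_total <- length(facial_nodes)
  if (n_total == 0) stop("no facial-expression muscles in metadata")
  facial_ids <- vapply(profiles, function(pr) pr$module_id, numeric(1))[
    vapply(profiles, function(pr)
      pr$label %in% c("left_facial", "right_facial", "main_facial"),
      logical(1))]
  n_in <- sum(p[facial_nodes] %in% facial_ids)
  structure(list(taxon_id = taxon_id,
                 n_in_facial = as.integer(n_in),
                 n_total_facial = as.integer(n_total),
                 percent = facial_inclusion_percent(n_in, n_total)),
            class = "facial_inclusion")
}

#' @export
print.facial_inclusion <- function(x, ...) {
  cat(sprintf("facial inclusion for '%s': %d of %d facial muscles (%d%%)\n",
              x$taxon_id, x$n_in_facial, x$n_total_facial, x$percent))
  invisible(x)
}

#' Facial-module asymmetry summary
#'
#' Summarizes the facial-module configuration of one taxon from its labeled
#' module profiles: whether a single bilateral `main_facial` module exists,
#' whether separate left/right facial modules exist, and whether any facial
#' module mixes body sides (`facial_modules_asymmetric`). Pure left plus
#' pure right modules is the plesiomorphic pattern; a main facial module or
#' side-mixing left/right modules is the anthropoid pattern.
#'
#' @param profiles List of `module_profile` objects.
#' @param taxon_id Taxon label.
#' @return One-row data frame with the three flags plus facial module count.
#' @export
asymmetry_report <- function(profiles, taxon_id = "unnamed_taxon") {
  labels <- vapply(profiles, function(p) p$label, character(1))
  asym <- vapply(profiles, function(p) p$asymmetric, logical(1))
  has_main <- any(labels == "main_facial")
  has_lr <- any(labels == "left_facial") || any(labels == "right_facial")
  data.frame(
    taxon_id = taxon_id,
    has_main_facial = has_main,
    has_left_right_facial = has_lr,
    facial_modules_asymmetric = has_main || any(asym),
    n_facial_modules = sum(labels %in%
                             c("left_facial", "right_facial", "main_facial")),
    stringsAsFactors = FALSE
  )
}
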