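#' Specification for a synthetic musculoskeletal network
#'
#' The generator emulates the structure of a head-and-neck muscle-bone
#' network: a connected skeletal scaffold (bones and laryngeal cartilages),
#' muscles of degree >= 2 attached mostly to skeletal units of their own
#' anatomical block, mirrored left/right anatomy with median elements, and
#' planted modules (left/right facial, laryngeal, suprahyoid-tongue,
#' postcranial, neurocranial). Defaults are sized to a realistic muscle-bone
#' network: 37 skeletal units and 129 muscles (N = 166, inside the published
#' musculoskeletal range of roughly 141-175), with 24 facial-expression
#' muscles per side and a target density band of 0.029-0.035, the band
#' spanned by published muscle-bone networks.
#'
#' @param n_bones_median,n_bones_per_side Median and per-side skeletal unit
#'   counts (laryngeal cartilages included).
#' @param n_muscles_per_side,n_muscles_median Sided and median muscle counts.
#' @param p_in,p_out Relative attachment weight for a skeletal target inside
#'   versus outside the muscle's planted block (also used for scaffold
#'   edges); `p_in > p_out` plants recoverable modules.
#' @param asymmetry_rate Probability that a sided muscle attachment is
#'   flipped to the mirror-image target on the opposite side, creating the
#'   anthropoid-like mixing of sides within facial modules. 0 gives a
#'   perfectly mirror-symmetric network (the plesiomorphic pattern).
#' @param extra_bone_edges Extra scaffold links sampled on the left+median
#'   half beyond the spanning tree (mirrored to the right).
#' @param extra_attachment_prob,extra_attachment_max Each muscle attaches to
#'   2 skeletal units (origin + insertion) plus
#'   `Binomial(extra_attachment_max, extra_attachment_prob)` extra targets,
#'   allowing platysma-like sheets.
#' @param target_density_band Accepted density interval `(lo, hi)`;
#'   generation is rejected and resampled until D lands inside (at most 100
#'   tries).
#' @param seed Integer seed; the single RNG stream threaded through all
#'   sampling, so output is bit-reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bones_median = 15, n_bones_per_side = 11,
                           n_muscles_per_side = 63, n_muscles_median = 3,
                           p_in = 0.9, p_out = 0.05,
                           asymmetry_rate = 0,
                           extra_bone_edges = 18,
                           extra_attachment_prob = 0.35,
                           extra_attachment_max = 2,
                           target_density_band = c(0.029, 0.035),
                           seed = 1) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            asymmetry_rate >= 0, asymmetry_rate <= 1,
            length(target_density_band) == 2,
            target_density_band[1] <= target_density_band[2])
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Specification for a plain planted-partition (stochastic block) network
#'
#' Community-recovery benchmark without anatomical structure: `n_blocks`
#' equally sized groups, within-block edge probability `p_in`, between-block
#' probability `p_out`.
#'
#' @param n_blocks,block_size Number and size of planted blocks.
#' @param p_in,p_out Within/between edge probabilities.
#' @param seed Integer seed.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(n_blocks = 4, block_size = 12,
                         p_in = 0.9, p_out = 0.02, seed = 1) {
  stopifnot(n_blocks >= 1, block_size >= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  structure(as.list(environment()), class = "planted_spec")
}

# ---- anatomical roster -----------------------------------------------------

pool_df <- function(name, block, tissue, group, facial = FALSE)
  data.frame(name = name, block = block, tissue = tissue, group = group,
             facial = facial, stringsAsFactors = FALSE)

# name pools per (block, placement); recycled with numeric suffixes if a
# requested count exceeds the pool
roster_pools <- function() {
  facial_muscles <- c(
    "platysma", "risorius", "occipitalis", "auricularis_posterior",
    "auricularis_anterior", "auricularis_superior", "zygomaticus_major",
    "zygomaticus_minor", "frontalis", "temporoparietalis",
    "orbicularis_oculi", "depressor_supercilii", "corrugator_supercilii",
    "levator_labii_superioris_alaeque_nasi", "procerus", "buccinatorius",
    "levator_labii_superioris", "nasalis", "depressor_septi_nasi",
    "levator_anguli_oris", "orbicularis_oris", "depressor_labii_inferioris",
    "depressor_anguli_oris", "mentalis")
  list(
    median_skeletal = rbind(
      pool_df(c("occipital", "sphenoid", "ethmoid", "frontal", "vomer",
                "mandible"), "neurocranial", "bone", "skeletal"),
      pool_df(c("cricoid_cartilage", "thyroid_cartilage"), "laryngeal",
              "cartilage", "skeletal"),
      pool_df("hyoid_body", "suprahyoid_tongue", "bone", "skeletal"),
      pool_df(c("sternum", "atlas", "axis", "cervical_vertebra_3",
                "cervical_vertebra_4", "cervical_vertebra_5"),
              "postcranial", "bone", "skeletal")),
    side_skeletal = rbind(
      pool_df(c("maxilla", "zygomatic", "nasal", "lacrimal", "palatine",
                "premaxilla"), "facial", "bone", "skeletal"),
      pool_df(c("parietal", "temporal"), "neurocranial", "bone", "skeletal"),
      pool_df("arytenoid_cartilage", "laryngeal", "cartilage", "skeletal"),
      pool_df(c("clavicle", "scapula"), "postcranial", "bone", "skeletal")),
    side_muscles = rbind(
      pool_df(facial_muscles, "facial", "muscle", "hyoid", facial = TRUE),
      pool_df(c("temporalis", "masseter", "pterygoideus_medialis",
                "pterygoideus_lateralis", "tensor_tympani", "stapedius"),
              "neurocranial", "muscle",
              c(rep("mandibular", 5), "hyoid")),
      pool_df(c("constrictor_pharyngis_superior", "constrictor_pharyngis_medius",
                "constrictor_pharyngis_inferior", "stylopharyngeus",
                "levator_veli_palatini", "tensor_veli_palatini",
                "palatopharyngeus"), "neurocranial", "muscle",
              c(rep("branchial", 5), "mandibular", "branchial")),
      pool_df(c("rectus_superior", "rectus_inferior", "rectus_medialis",
                "rectus_lateralis", "obliquus_superior", "obliquus_inferior",
                "levator_palpebrae_superioris"), "neurocranial", "muscle",
              "extraocular"),
      pool_df(c("digastricus_anterior", "digastricus_posterior",
                "mylohyoideus", "stylohyoideus", "geniohyoideus",
                "genioglossus", "hyoglossus", "styloglossus"),
              "suprahyoid_tongue", "muscle",
              c("mandibular", "hyoid", "mandibular", "hyoid",
                rep("hypobranchial", 4))),
      pool_df(c("cricothyroideus", "cricoarytenoideus_posterior",
                "cricoarytenoideus_lateralis", "thyroarytenoideus",
                "vocalis"), "laryngeal", "muscle", "branchial"),
      pool_df(c("trapezius", "sternocleidomastoideus", "omohyoideus",
                "sternohyoideus", "sternothyroideus", "thyrohyoideus"),
              "postcranial", "muscle",
              c("branchial", "branchial", rep("hypobranchial", 4)))),
    median_muscles = rbind(
      pool_df("intrinsic_tongue", "suprahyoid_tongue", "muscle", "hypobranchial"),
      pool_df("arytenoideus_transversus", "laryngeal", "muscle", "branchial"),
      pool_df("musculus_uvulae", "neurocranial", "muscle", "branchial"))
  )
}

take_from_pool <- function(pool, n) {
  if (n <= nrow(pool)) return(pool[seq_len(n), , drop = FALSE])
  extra <- pool[rep(seq_len(nrow(pool)), length.out = n - nrow(pool)), ,
                drop = FALSE]
  extra$name <- sprintf("%s_v%02d", extra$name,
                        1 + (seq_len(nrow(extra)) - 1) %/% nrow(pool) + 1)
  rbind(pool, extra)
}

# full node roster: one row per node with name, tissue, side, group, block,
# facial flag; sided entries are duplicated with _L/_R suffixes
build_roster <- function(spec) {
  pools <- roster_pools()
  med_sk <- take_from_pool(pools$median_skeletal, spec$n_bones_median)
  side_sk <- take_from_pool(pools$side_skeletal, spec$n_bones_per_side)
  side_mu <- take_from_pool(pools$side_muscles, spec$n_muscles_per_side)
  med_mu <- take_from_pool(pools$median_muscles, spec$n_muscles_median)

  mirror_rows <- function(df) {
    left <- df; right <- df
    left$name <- paste0(df$name, "_L"); left$side <- "left"
    right$name <- paste0(df$name, "_R"); right$side <- "right"
    rbind(left, right)
  }
  med_sk$side <- "median"; med_mu$side <- "median"
  roster <- rbind(med_sk, mirror_rows(side_sk), med_mu, mirror_rows(side_mu))
  # sided facial nodes belong to side-specific planted blocks
  roster$block <- ifelse(roster$block == "facial" & roster$side == "left",
                         "facial_L",
                  ifelse(roster$block == "facial" & roster$side == "right",
                         "facial_R", roster$block))
  rownames(roster) <- NULL
  roster
}

mirror_name <- function(x) {
  out <- x
  l <- grepl("_L$", x); r <- grepl("_R$", x)
  out[l] <- sub("_L$", "_R", x[l])
  out[r] <- sub("_R$", "_L", x[r])
  out
}

block_weight <- function(own_block, target_blocks, p_in, p_out) {
  # facial_L and facial_R count as the same anatomical region for weighting
  strip <- function(b) sub("^facial_[LR]$", "facial", b)
  w <- ifelse(strip(target_blocks) == strip(own_block), p_in, p_out)
  if (sum(w) == 0) w <- rep(1, length(w))
  w
}

sample_idx <- function(n, size, prob) {
  # sample() with a length-1 first argument would misbehave
  if (n == 1) return(rep(1L, size))
  sample.int(n, size, prob = prob)
}

# ---- generators ------------------------------------------------------------

#' Generate a synthetic network with known planted structure
#'
#' Dispatches on the spec class: [synthetic_spec()] builds a mirrored
#' musculoskeletal-like network (connected skeletal scaffold, block-weighted
#' muscle attachments, optional side asymmetrization, density calibrated
#' into the target band by rejection); [planted_spec()] builds a plain
#' stochastic block model. Both are deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()] or [planted_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A list with `network` (an [anatomical_network()]), `planted`
#'   (an `anna_partition` of the planted blocks), `metadata` (the node
#'   metadata data frame) and `seed`.
#' @export
generate_network <- function(spec, seed = NULL) UseMethod("generate_network")

#' @export
generate_network.planted_spec <- function(spec, seed = NULL) {
  seed <- if (is.null(seed)) spec$seed else seed
  set.seed(seed)
  n <- spec$n_blocks * spec$block_size
  nodes <- sprintf("unit_%03d", seq_len(n))
  block <- rep(seq_len(spec$n_blocks), each = spec$block_size)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], spec$p_in, spec$p_out)
  on <- stats::runif(nrow(pairs)) < p
  edges <- cbind(nodes[pairs[on, 1]], nodes[pairs[on, 2]])
  net <- suppressWarnings(
    anatomical_network(nodes, edges, taxon_id = sprintf("planted_seed%d", seed)))
  planted <- as_partition(setNames(block, nodes), net, method = "planted")
  list(network = net, planted = planted, metadata = net$meta, seed = seed)
}

#' @export
generate_network.synthetic_spec <- function(spec, seed = NULL) {
  seed <- if (is.null(seed)) spec$seed else seed
  set.seed(seed)
  roster <- build_roster(spec)
  skel <- roster[roster$tissue != "muscle", , drop = FALSE]
  musc <- roster[roster$tissue == "muscle", , drop = FALSE]
  half_skel <- skel[skel$side != "right", , drop = FALSE]   # median + left
  if (nrow(half_skel) < 2) stop("infeasible spec: not enough skeletal nodes")

  for (try in seq_len(100)) {
    edges <- generate_half_edges(spec, roster, skel, musc, half_skel)
    edges <- mirror_and_asymmetrize(edges, roster, spec)
    net <- suppressWarnings(anatomical_network(
      roster$name, edges,
      metadata = roster[, c("name", "tissue", "side", "group", "facial")] |>
        stats::setNames(c("node", "tissue", "side", "group",
                          "is_facial_expression")),
      taxon_id = sprintf("synthetic_seed%d", seed)))
    d <- net_density(net)
    if (d >= spec$target_density_band[1] && d <= spec$target_density_band[2])
      break
    if (try == 100)
      stop(sprintf("density calibration failed after 100 tries (last D = %.4f)", d))
  }

  planted <- as_partition(setNames(roster$block, roster$name), net,
                          method = "planted")
  list(network = net, planted = planted, metadata = net$meta, seed = seed)
}

# scaffold tree + extra skeletal links + muscle attachments, all on the
# median/left half (sided right structures are produced by mirroring)
generate_half_edges <- function(spec, roster, skel, musc, half_skel) {
  # spanning tree over the half skeleton, rooted at a median node so the
  # mirrored halves share the median spine and the full scaffold is connected
  ord <- c(which(half_skel$side == "median")[1],
           sample(setdiff(seq_len(nrow(half_skel)),
                          which(half_skel$side == "median")[1])))
  added <- ord[1]
  tree <- matrix(character(0), ncol = 2)
  for (v in ord[-1]) {
    w <- block_weight(half_skel$block[v], half_skel$block[added],
                      spec$p_in, spec$p_out)
    parent <- added[sample_idx(length(added), 1, w)]
    tree <- rbind(tree, c(half_skel$name[parent], half_skel$name[v]))
    added <- c(added, v)
  }

  # extra skeletal links beyond the tree, block-weighted
  pairs <- which(upper.tri(matrix(0, nrow(half_skel), nrow(half_skel))),
                 arr.ind = TRUE)
  wp <- block_weight_pairs(half_skel$block[pairs[, 1]],
                           half_skel$block[pairs[, 2]],
                           spec$p_in, spec$p_out)
  n_extra <- min(spec$extra_bone_edges, nrow(pairs))
  pick <- sample_idx(nrow(pairs), n_extra, wp)
  extra <- cbind(half_skel$name[pairs[pick, 1]], half_skel$name[pairs[pick, 2]])

  # muscle attachments: 2 + binomial extras, block-weighted targets drawn
  # from the muscle's own side plus the median skeleton
  half_musc <- musc[musc$side != "right", , drop = FALSE]
  att <- lapply(seq_len(nrow(half_musc)), function(i) {
    m <- half_musc[i, ]
    cand <- if (m$side == "median") skel[skel$side == "median", , drop = FALSE]
            else skel[skel$side != "right", , drop = FALSE]
    if (nrow(cand) == 0)
      stop("infeasible spec: no attachment targets for ", m$name)
    n_att <- 2 + stats::rbinom(1, spec$extra_attachment_max,
                               spec$extra_attachment_prob)
    n_att <- min(n_att, nrow(cand))
    w <- block_weight(m$block, cand$block, spec$p_in, spec$p_out)
    targets <- cand$name[sample_idx(nrow(cand), n_att, w)]
    targets <- unique(targets)
    while (length(targets) < min(2, nrow(cand))) {
      more <- cand$name[sample_idx(nrow(cand), 1, w)]
      targets <- unique(c(targets, more))
    }
    cbind(rep(m$name, length(targets)), targets)
  })
  rbind(tree, extra, do.call(rbind, att))
}

block_weight_pairs <- function(b1, b2, p_in, p_out) {
  strip <- function(b) sub("^facial_[LR]$", "facial", b)
  w <- ifelse(strip(b1) == strip(b2), p_in, p_out)
  if (sum(w) == 0) w <- rep(1, length(w))
  w
}

mirror_and_asymmetrize <- function(edges, roster, spec) {
  side_of <- setNames(roster$side, roster$name)
  tissue_of <- setNames(roster$tissue, roster$name)
  mirrored <- cbind(mirror_name(edges[, 1]), mirror_name(edges[, 2]))
  keep <- !(mirrored[, 1] == edges[, 1] & mirrored[, 2] == edges[, 2])
  all_edges <- rbind(edges, mirrored[keep, , drop = FALSE])
  if (spec$asymmetry_rate > 0) {
    is_muscle_edge <- tissue_of[all_edges[, 1]] == "muscle" |
      tissue_of[all_edges[, 2]] == "muscle"
    for (k in which(is_muscle_edge)) {
      mcol <- if (tissue_of[all_edges[k, 1]] == "muscle") 1 else 2
      scol <- 3 - mcol
      if (side_of[all_edges[k, mcol]] != "median" &&
          side_of[all_edges[k, scol]] != "median" &&
          stats::runif(1) < spec$asymmetry_rate) {
        all_edges[k, scol] <- mirror_name(all_edges[k, scol])
      }
    }
  }
  all_edges
}

#' Module-recovery experiment on synthetic networks
#'
#' Generates `n_reps` networks from a spec (one per seed), runs
#' [detect_modules_greedy()] on each, and scores recovery of the planted
#' partition by [adjusted_rand()].
#'
#' @param spec A [synthetic_spec()] or [planted_spec()] with `p_in > p_out`
#'   for a recovery scenario (equal probabilities give the null).
#' @param n_reps Number of replicates (>= 1).
#' @param seeds Integer vector of seeds, one per replicate; defaults to
#'   `spec$seed + 0:(n_reps-1)`.
#' @return List with `ari` (vector), `mean_ari`, `min_ari`, `seeds`.
#' @export
recovery_experiment <- function(spec, n_reps = 20, seeds = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(seeds)) seeds <- spec$seed + seq_len(n_reps) - 1
  if (length(seeds) != n_reps) stop("need one seed per replicate")
  ari <- vapply(seeds, function(s) {
    gen <- generate_network(spec, seed = s)
    det <- detect_modules_greedy(gen$network)
    adjusted_rand(det, gen$planted)
  }, numeric(1))
  list(ari = ari, mean_ari = mean(ari), min_ari = min(ari), seeds = seeds)
}
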