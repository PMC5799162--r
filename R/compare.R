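#' Reference values from the published comparative analysis
#'
#' Printed parameter values, facial-inclusion fractions and module counts for
#' head and neck networks of 22 primate genera and three outgroup taxa, as
#' transcribed from a published comparative analysis. These are fixtures for
#' regression checks ([check_against_fixture()]) and for rank-level claims
#' ([rank_and_correlate()]); they are not recomputable from this package
#' alone, because the underlying per-taxon connectivity matrices are
#' supplementary material of the original study.
#'
#' Two printed percentages disagree with their printed fractions
#' (Pongo 59 vs 24/46 = 52; Lemur 54 vs 24/44 = 55 under half-up rounding);
#' both the printed percent and the fraction are carried, uncorrected.
#'
#' @return A data frame with columns `taxon`, `kind` (`bones_only` or
#'   `muscle_bone`), `quantity` (`N`, `K`, `D`, `L`, `facial_percent`,
#'   `module_count`), `value`, `numerator`, `denominator` (for fractions),
#'   `decimals` (printed precision) and `source` (provenance descriptor).
#' @export
reported_values <- function() {
  src_param <- "published head and neck network parameter comparison"
  src_facial <- "published facial-muscle inclusion percentages"
  src_modules <- "published module counts (figure captions)"
  row <- function(taxon, kind, quantity, value, numerator = NA, denominator = NA,
                  decimals = 0, source = src_param)
    data.frame(taxon = taxon, kind = kind, quantity = quantity, value = value,
               numerator = numerator, denominator = denominator,
               decimals = decimals, source = source, stringsAsFactors = FALSE)
  rbind(
    row("Homo", "bones_only", "N", 37),
    row("Homo", "bones_only", "K", 72),
    row("Homo", "bones_only", "D", 0.108, decimals = 3),
    row("Pan_troglodytes", "bones_only", "K", 70),
    row("Pongo", "bones_only", "K", 69),
    row("Lemur", "bones_only", "N", 41),
    row("Gorilla", "bones_only", "L", 2.65, decimals = 2),
    row("Tarsius", "bones_only", "L", 2.65, decimals = 2),
    row("Mus", "bones_only", "L", 2.3, decimals = 1),
    row("Homo", "muscle_bone", "N", 157),
    row("Homo", "muscle_bone", "D", 0.029, decimals = 3),
    row("Tupaia", "muscle_bone", "N", 161),
    row("Tupaia", "muscle_bone", "D", 0.029, decimals = 3),
    row("Mus", "muscle_bone", "N", 175),
    row("Mus", "muscle_bone", "D", 0.029, decimals = 3),
    row("Saimiri", "muscle_bone", "N", 141),
    row("Saimiri", "muscle_bone", "D", 0.035, decimals = 3),
    row("Homo", "muscle_bone", "facial_percent", 75, 36, 48, source = src_facial),
    row("Pan_troglodytes", "muscle_bone", "facial_percent", 66, 29, 44, source = src_facial),
    row("Pan_paniscus", "muscle_bone", "facial_percent", 68, 30, 44, source = src_facial),
    row("Gorilla", "muscle_bone", "facial_percent", 81, 36, 44, source = src_facial),
    row("Pongo", "muscle_bone", "facial_percent", 59, 24, 46, source = src_facial),
    row("Hylobates", "muscle_bone", "facial_percent", 60, 28, 46, source = src_facial),
    row("Macaca", "muscle_bone", "facial_percent", 72, 33, 46, source = src_facial),
    row("Callithrix", "muscle_bone", "facial_percent", 63, 24, 38, source = src_facial),
    row("Tarsius", "muscle_bone", "facial_percent", 52, 22, 42, source = src_facial),
    row("Lemur", "muscle_bone", "facial_percent", 54, 24, 44, source = src_facial),
    row("Cynocephalus", "muscle_bone", "facial_percent", 66, 28, 42, source = src_facial),
    row("Tupaia", "muscle_bone", "facial_percent", 54, 25, 46, source = src_facial),
    row("Mus", "muscle_bone", "facial_percent", 31, 14, 44, source = src_facial),
    row("Mus", "muscle_bone", "module_count", 20, source = src_modules),
    row("Tupaia", "muscle_bone", "module_count", 19, source = src_modules),
    row("Cynocephalus", "muscle_bone", "module_count", 15, source = src_modules),
    row("Lemur", "muscle_bone", "module_count", 15, source = src_modules),
    row("Tarsius", "muscle_bone", "module_count", 16, source = src_modules),
    row("Callithrix", "muscle_bone", "module_count", 12, source = src_modules),
    row("Macaca", "muscle_bone", "module_count", 18, source = src_modules),
    row("Hylobates", "muscle_bone", "module_count", 17, source = src_modules),
    row("Pongo", "muscle_bone", "module_count", 12, source = src_modules),
    row("Gorilla", "muscle_bone", "module_count", 17, source = src_modules),
    row("Pan_troglodytes", "muscle_bone", "module_count", 12, source = src_modules),
    row("Pan_paniscus", "muscle_bone", "module_count", 11, source = src_modules),
    row("Homo", "muscle_bone", "module_count", 11, source = src_modules)
  )
}

#' Assemble a cross-taxon comparison table
#'
#' Runs [parameter_set()], [detect_modules_greedy()], [profile_modules()],
#' [facial_inclusion()] and [asymmetry_report()] per input network and binds
#' one row per (taxon, network kind). Facial-inclusion cells are `NA` for
#' networks without facial-expression muscles (e.g. bones-only networks).
#'
#' @param networks List of [anatomical_network()] objects.
#' @param kinds Character vector (recycled) of network kinds, `"bones_only"`
#'   or `"muscle_bone"`.
#' @param config A [classify_config()].
#' @return A data frame of class `taxon_table`, with a `provenance`
#'   attribute marking every cell source as `"computed"`.
#' @export
build_table <- function(networks, kinds = "muscle_bone",
                        config = classify_config()) {
  if (length(networks) == 0) stop("no networks supplied")
  kinds <- rep_len(match.arg(kinds, c("bones_only", "muscle_bone"),
                             several.ok = TRUE), length(networks))
  keys <- paste(vapply(networks, function(n) n$taxon_id, character(1)), kinds)
  if (anyDuplicated(keys))
    stop("duplicate (taxon_id, kind): ", keys[duplicated(keys)][1])
  rows <- lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    ps <- parameter_set(net)
    part <- detect_modules_greedy(net)
    profs <- profile_modules(net, part, config = config)
    asym <- asymmetry_report(profs, taxon_id = net$taxon_id)
    fi <- if (any(net$meta$is_facial_expression))
      facial_inclusion(part, net$meta, profs, taxon_id = net$taxon_id)
    else list(n_in_facial = NA_integer_, n_total_facial = NA_integer_,
              percent = NA_integer_)
    data.frame(
      taxon_id = net$taxon_id, kind = kinds[i],
      N = ps$N, K = ps$K, D = ps$D, C = ps$C, L = ps$L, H = ps$H,
      connected = ps$connected,
      module_count = n_modules(part), Q = part$Q,
      facial_in = fi$n_in_facial, facial_total = fi$n_total_facial,
      facial_percent = fi$percent,
      has_main_facial = asym$has_main_facial,
      has_left_right_facial = asym$has_left_right_facial,
      facial_modules_asymmetric = asym$facial_modules_asymmetric,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- "computed"
  class(out) <- c("taxon_table", "data.frame")
  out
}

#' Spearman rank correlation between two table columns
#'
#' Rank-level association (average ranks at ties), the appropriate statistic
#' for claims argued by ranks — e.g. that taxa with more musculoskeletal
#' structures sit at the bottom of the density ranking.
#'
#' @param table A data frame (e.g. a `taxon_table` or a fixture subset).
#' @param x,y Column names.
#' @return List with `rho`, `n`, `method` and a `ranking` data frame sorted
#'   by `x`.
#' @export
rank_and_correlate <- function(table, x, y) {
  stopifnot(x %in% names(table), y %in% names(table))
  keep <- complete.cases(table[, c(x, y)])
  xs <- table[[x]][keep]
  ys <- table[[y]][keep]
  if (length(xs) < 3) stop("need at least 3 rows with both columns present")
  if (sd(xs) == 0 || sd(ys) == 0) stop("zero variance in a column")
  rho <- cor(xs, ys, method = "spearman")
  ranking <- data.frame(table[keep, , drop = FALSE],
                        rank_x = rank(xs), rank_y = rank(ys))
  ranking <- ranking[order(xs), , drop = FALSE]
  list(rho = rho, n = length(xs), method = "spearman", ranking = ranking)
}

#' Check a computed table against published reference values
#'
#' For every fixture row, the matching computed cell (same taxon, kind and
#' quantity) is rounded to the fixture's printed precision and compared for
#' equality. Fixture rows without a computed counterpart are reported as
#' `"unchecked"` — the published per-taxon matrices are supplementary
#' material, so most reference values are checkable only when those matrices
#' are supplied. `module_count` rows are always reported `"excluded"`:
#' module counts depend on the detection algorithm and are not a regression
#' surface.
#'
#' @param table A `taxon_table` from [build_table()]. Taxon matching uses
#'   `taxon_id` against the fixture's `taxon`.
#' @param fixture A fixture data frame, by default [reported_values()].
#' @return A data frame with one row per fixture value: `taxon`, `kind`,
#'   `quantity`, `reference`, `computed`, `status`
#'   (`match`/`mismatch`/`unchecked`/`excluded`) and `source`.
#' @export
check_against_fixture <- function(table, fixture = reported_values()) {
  col_for <- c(N = "N", K = "K", D = "D", C = "C", L = "L", H = "H",
               facial_percent = "facial_percent", module_count = "module_count")
  out <- lapply(seq_len(nrow(fixture)), function(i) {
    fx <- fixture[i, ]
    computed <- NA_real_
    status <- "unchecked"
    if (fx$quantity == "module_count") {
      status <- "excluded"
    } else {
      hit <- which(table$taxon_id == fx$taxon & table$kind == fx$kind)
      col <- col_for[[fx$quantity]]
      if (length(hit) == 1 && !is.null(table[[col]]) &&
          !is.na(table[[col]][hit])) {
        computed <- round(table[[col]][hit], fx$decimals)
        status <- if (isTRUE(all.equal(computed, fx$value))) "match" else "mismatch"
      }
    }
    data.frame(taxon = fx$taxon, kind = fx$kind, quantity = fx$quantity,
               reference = fx$value, computed = computed, status = status,
               source = fx$source, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
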