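# Frozen micro-fixtures: the dataset-composition table and the worked
# fill-rule/metric examples used by the regression tests. Fixtures store
# count profiles and expected values with provenance notes, never real
# assay data.

fixture_registry <- function() {
  ext <- function(f) system.file("extdata", f, package = "fluidsim")
  profiles <- jsonlite::fromJSON(ext("fillrule_profiles.json"))
  fixtures <- list(
    table1_counts = function() {
      counts <- readr::read_csv(ext("table1_counts.csv"), show_col_types = FALSE)
      list(name = "table1_counts",
           inputs = counts,
           expected = NULL,
           provenance = "dataset numerical-composition table (5 targets x 5 dataset columns)")
    },
    mcc_micro = function() {
      raw <- jsonlite::fromJSON(ext("mcc_micro.json"))
      list(name = "mcc_micro", inputs = raw, expected = raw,
           provenance = "hand confusion tables with directly evaluated metrics")
    }
  )
  for (nm in names(profiles)) {
    local({
      nm2 <- nm
      fixtures[[nm2]] <<- function() {
        p <- profiles[[nm2]]
        list(name = nm2, inputs = p$inputs, expected = p$expected,
             provenance = p$provenance)
      }
    })
  }
  fixtures
}

#' Load a frozen micro-fixture
#'
#' Available fixtures: `table1_counts` (the 25-cell dataset-composition
#' table: per target, the internal train/test, both federated, and public
#' set sizes with inactive/active splits), the three fill-rule eligibility
#' profiles `fillrule_gaba` (5,085 eligible positives),
#' `fillrule_cox2_mlp` (9,465) and `fillrule_cox2_sohn` (7,767), and
#' `mcc_micro` (hand confusion tables). Fill-rule fixtures store count
#' profiles only; tests synthesize dummy consolidated predictions matching
#' the profile.
#'
#' @param name Fixture name.
#' @return List with `name`, `inputs`, `expected`, `provenance`.
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    abort(sprintf("unknown fixture '%s'; available: %s",
                  name, paste(sort(names(reg)), collapse = ", ")))
  }
  reg[[name]]()
}

#' Synthesize consolidated predictions matching an eligibility profile
#'
#' Builds a dummy consolidated-prediction table with the requested numbers
#' of eligible positives and negatives (all above the reliability
#' threshold, distinct decidabilities) so fill-rule behaviour can be
#' exercised against count profiles.
#'
#' @param n_pos_eligible,n_neg_eligible Eligible records per class.
#' @param reliability_min The filter threshold the records must clear.
#' @param seed Seed for the arbitrary decidability draws.
#' @return Tibble in the [consolidate()] output format.
#' @export
synthesize_consolidated <- function(n_pos_eligible, n_neg_eligible,
                                    reliability_min = 0.005, seed = 1) {
  n <- n_pos_eligible + n_neg_eligible
  withr::with_seed(seed, {
    tibble(
      molecule_id = sprintf("mol%07d", seq_len(n)),
      consensus_label = c(rep(1L, n_pos_eligible), rep(0L, n_neg_eligible)),
      consensus_decidability = sample(seq_len(n)) / (n + 1),
      consensus_reliability = runif(n, min = reliability_min, max = 1),
      n_members = 3L,
      member_agreement = 1
    )
  })
}
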