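#' Published chamber-period marginal means (plausibility anchors)
#'
#' Estimated marginal means reported by the motivating 12-cow hemp-vs-soy
#' crossover trial for the respiration-chamber period, used only as scale
#' and plausibility anchors: they are model-adjusted group means of raw
#' data that are not publicly deposited, so no numeric reproduction is
#' claimed or attempted.
#'
#' @return A list with elements `HEMP` and `CON` (each a named numeric
#'   vector: `dmi_kg_d`, `mbw_kg075`, `ecm_kg_d`, `milk_kg_d`, `fat_pct`,
#'   `protein_pct`, `lactose_pct`, `ch4_l_d`, `mrq`, `hp_per_mbw_kj`,
#'   `eb_mj_d`, `n_urine_g_d`, `n_feces_g_d`, `cp_degradability_pct`,
#'   `dig_dm_pct`, `dig_om_pct`, `dig_energy_pct`) and
#'   `me_mj_per_kg_dm` (feed energy density, both diets).
#' @export
anchor_means <- function() {
  list(
    HEMP = c(dmi_kg_d = 17.6, mbw_kg075 = 124, ecm_kg_d = 29.5,
             milk_kg_d = 29.8, fat_pct = 4.06, protein_pct = 3.63,
             lactose_pct = 4.99, ch4_l_d = 511, mrq = 0.92,
             hp_per_mbw_kj = 1135, eb_mj_d = -32.7,
             n_urine_g_d = 93.2, n_feces_g_d = 151.0,
             cp_degradability_pct = 64.1, dig_dm_pct = 65.7,
             dig_om_pct = 67.4, dig_energy_pct = 65.1),
    CON = c(dmi_kg_d = 17.4, mbw_kg075 = 127, ecm_kg_d = 30.1,
            milk_kg_d = 29.7, fat_pct = 4.23, protein_pct = 3.59,
            lactose_pct = 4.99, ch4_l_d = 522, mrq = 0.91,
            hp_per_mbw_kj = 1138, eb_mj_d = -38.1,
            n_urine_g_d = 116.1, n_feces_g_d = 147.0,
            cp_degradability_pct = 65.2, dig_dm_pct = 67.5,
            dig_om_pct = 68.9, dig_energy_pct = 67.1),
    me_mj_per_kg_dm = 11.45
  )
}
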