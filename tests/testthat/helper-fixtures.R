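# Constructors for small hand-specified model-fit and classification
# tables used by the set-arithmetic and catalogue tests.

make_fit_table <- function(ids, up = character(), down = character(),
                           avg_A = 10) {
  lfc <- ifelse(ids %in% up, 1.5, ifelse(ids %in% down, -1.5, 0))
  adj <- ifelse(ids %in% c(up, down), 0.001, 0.9)
  data.frame(target_id = ids, logFC = lfc,
             AveExpr = rep(avg_A, length(ids)),
             t = lfc * 10, P.Value = adj / 10, adj.P.Val = adj,
             B = ifelse(adj < 0.05, 3, -3),
             stringsAsFactors = FALSE)
}

small_study <- function(n_targets = 250, seed = 11) {
  simulate_study(
    n_targets,
    layout = array_layout(n_antisense_controls = 40),
    seed = seed)
}
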