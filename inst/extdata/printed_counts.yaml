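# Contingency counts and printed summary statistics from the published
# staging-concordance tables that this package's statistics module
# reproduces (48 machine-evaluated cases, 72 radiologist-read cases).
# Confusion cells are [predicted IA & true IA, predicted IA & true IB,
#                      predicted IB & true IA, predicted IB & true IB].
table2:
  ai_t1c:
    cells: [30, 3, 7, 8]
    printed_accuracy_pct: 79.2
    printed_over_rate_pct: 70.0
    citation: "concordance study, accuracy table, contrast-enhanced T1w block"
  ai_t2:
    cells: [29, 5, 9, 5]
    printed_accuracy_pct: 70.8
    printed_over_rate_pct: 64.3
    citation: "concordance study, accuracy table, T2w block"
  radiologists:
    cells: [39, 2, 14, 17]
    printed_accuracy_pct: 77.8
    printed_over_rate_pct: 87.5
    citation: "concordance study, accuracy table, radiologists block"
chi2_vs_radiologists:
  # correct/incorrect counts of each method against the radiologists
  ai_t1c:
    printed_chi2: 0.033
    printed_p: 0.856
    citation: "concordance study, accuracy table footnote"
  ai_t2:
    printed_chi2: 0.738
    printed_p: 0.392
    citation: "concordance study, accuracy table footnote"
table3:
  # condition-effect blocks: confusion cells with / without the condition
  leiomyoma:
    ai_t1c:
      cells_with: [9, 1, 5, 0]
      cells_without: [21, 2, 2, 8]
      printed_accuracy_with_pct: 60
      printed_accuracy_without_pct: 87.9
      printed_p: 0.027
      citation: "concordance study, concomitant-condition table, leiomyoma x T1w"
    ai_t2:
      cells_with: [8, 1, 6, 1]
      cells_without: [21, 4, 3, 4]
      printed_accuracy_with_pct: 56.3
      printed_accuracy_without_pct: 78.1
      printed_p: 0.115
      citation: "concordance study, concomitant-condition table, leiomyoma x T2w"
    radiologists:
      cells_with: [16, 1, 8, 4]
      cells_without: [23, 1, 6, 13]
      printed_accuracy_with_pct: 69
      printed_accuracy_without_pct: 83.7
      printed_p: 0.140
      citation: "concordance study, concomitant-condition table, leiomyoma x radiologists"
  histology:
    ai_t1c:
      cells_with: [26, 2, 5, 4]
      cells_without: [4, 1, 2, 4]
      printed_accuracy_with_pct: 81.1
      printed_accuracy_without_pct: 72.7
      printed_p: 0.549
      citation: "concordance study, concomitant-condition table, histology x T1w (with = type I)"
    ai_t2:
      cells_with: [25, 4, 7, 2]
      cells_without: [4, 1, 2, 3]
      printed_accuracy_with_pct: 71.1
      printed_accuracy_without_pct: 70
      printed_p: 0.727
      citation: "concordance study, concomitant-condition table, histology x T2w (with = type I)"
    radiologists:
      cells_with: [35, 1, 11, 12]
      cells_without: [4, 1, 3, 5]
      printed_accuracy_with_pct: 79.7
      printed_accuracy_without_pct: 69.2
      printed_p: 0.413
      citation: "concordance study, concomitant-condition table, histology x radiologists (with = type I)"
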