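# Reproduction of the published concordance tables from their printed
# contingency counts.

confusion_from_cells <- function(cells) {
  # cells: [pred IA & true IA, pred IA & true IB, pred IB & true IA,
  #         pred IB & true IB]
  matrix(as.numeric(cells), 2, 2, byrow = TRUE,
         dimnames = list(pred = c("IA", "IB"), true = c("IA", "IB")))
}

stages_from_confusion <- function(cm) {
  pred <- rep(rep(c("IA", "IB"), each = 2), times = as.vector(t(cm)))
  true <- rep(rep(c("IA", "IB"), times = 2), times = as.vector(t(cm)))
  list(pred = pred, true = true)
}

#' Recompute the published concordance tables from their printed counts
#'
#' Every accuracy, over-diagnosis rate and chi-square p-value derivable
#' from the printed contingency counts of the source study's accuracy and
#' concomitant-condition tables is recomputed by this package's statistics
#' functions and compared against the printed value at its printed
#' precision (round-half-even). A handful of printed values are known not
#' to match their own printed counts; they are reported with
#' `match = FALSE`, not silently forced.
#'
#' @param counts_file Path to the printed-counts fixture; defaults to the
#'   copy shipped with the package.
#' @return A `printed_tables_report`: a tibble with columns `table`,
#'   `quantity`, `computed`, `printed`, `digits`, `match`, `citation`.
#' @export
reproduce_printed_tables <- function(counts_file = NULL) {
  counts_file <- counts_file %||%
    system.file("extdata", "printed_counts.yaml", package = "myoinvade")
  pc <- yaml::read_yaml(counts_file)
  rows <- list()
  add <- function(table, quantity, computed, printed, digits, citation) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      table = table, quantity = quantity, computed = computed,
      printed = printed, digits = digits,
      match = round(computed, digits) == printed, citation = citation
    )
  }

  # Accuracy table: accuracies and over-diagnosis rates per reader.
  correct_incorrect <- list()
  for (nm in names(pc$table2)) {
    blk <- pc$table2[[nm]]
    cm <- confusion_from_cells(blk$cells)
    st <- stages_from_confusion(cm)
    ds <- diagnostic_summary(st$pred, st$true)
    correct_incorrect[[nm]] <- c(ds$n_compatible, ds$n - ds$n_compatible)
    add("accuracy", paste0("accuracy_", nm), 100 * ds$accuracy,
        blk$printed_accuracy_pct, 1, blk$citation)
    add("accuracy", paste0("over_rate_", nm), 100 * ds$over_diagnosis_rate,
        blk$printed_over_rate_pct, 1, blk$citation)
  }

  # Chi-square of each machine reading against the radiologists
  # (correct/incorrect counts).
  for (nm in names(pc$chi2_vs_radiologists)) {
    blk <- pc$chi2_vs_radiologists[[nm]]
    tab <- rbind(correct_incorrect[[nm]], correct_incorrect$radiologists)
    ct <- pearson_chi2(tab)
    add("accuracy", paste0("chi2_", nm, "_vs_radiologists"), ct$chi2,
        blk$printed_chi2, 3, blk$citation)
    add("accuracy", paste0("p_", nm, "_vs_radiologists"), ct$p,
        blk$printed_p, 3, blk$citation)
  }

  # Condition-effect blocks: per-condition accuracies and the chi-square of
  # condition vs correctness.
  for (cond in names(pc$table3)) {
    for (nm in names(pc$table3[[cond]])) {
      blk <- pc$table3[[cond]][[nm]]
      acc <- lapply(list(blk$cells_with, blk$cells_without), function(cl) {
        cm <- confusion_from_cells(cl)
        st <- stages_from_confusion(cm)
        diagnostic_summary(st$pred, st$true)
      })
      dig_w <- printed_digits(blk$printed_accuracy_with_pct)
      dig_wo <- printed_digits(blk$printed_accuracy_without_pct)
      add(cond, paste0("accuracy_", nm, "_with"), 100 * acc[[1]]$accuracy,
          blk$printed_accuracy_with_pct, dig_w, blk$citation)
      add(cond, paste0("accuracy_", nm, "_without"), 100 * acc[[2]]$accuracy,
          blk$printed_accuracy_without_pct, dig_wo, blk$citation)
      tab <- rbind(
        c(acc[[1]]$n_compatible, acc[[1]]$n - acc[[1]]$n_compatible),
        c(acc[[2]]$n_compatible, acc[[2]]$n - acc[[2]]$n_compatible)
      )
      ct <- pearson_chi2(tab)
      add(cond, paste0("p_", cond, "_", nm), ct$p, blk$printed_p, 3,
          blk$citation)
    }
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("printed_tables_report", class(out))
  out
}

printed_digits <- function(x) {
  if (x == round(x)) 0L else 1L
}

#' @export
print.printed_tables_report <- function(x, ...) {
  cat(sprintf(
    "<printed_tables_report> %d quantities recomputed, %d match printed values\n",
    nrow(x), sum(x$match)
  ))
  mism <- x[!x$match, c("quantity", "computed", "printed")]
  if (nrow(mism)) {
    cat("  printed values not reproducible from their own printed counts:\n")
    for (i in seq_len(nrow(mism))) {
      cat(sprintf("    %s: computed %.4g, printed %.4g\n",
                  mism$quantity[i], mism$computed[i], mism$printed[i]))
    }
  }
  NextMethod()
}
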