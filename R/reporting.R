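#' Check flowchart conservation invariants
#'
#' Every stage must satisfy `input = kept + excluded` and consecutive
#' stages must telescope (`kept` of stage k equals `input` of stage k+1).
#' Inconsistent flowcharts are never rendered.
#'
#' @param counts Flowchart tibble with columns `stage`, `input`, `kept`,
#'   `excluded`.
#' @return `counts`, invisibly, when valid; otherwise an error.
#' @export
check_flowchart <- function(counts) {
  need <- c("stage", "input", "kept", "excluded")
  if (!all(need %in% names(counts))) {
    stop("flowchart needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- counts$input != counts$kept + counts$excluded
  if (any(bad)) {
    stop("flowchart conservation violated (input != kept + excluded) at ",
         "stage(s): ", paste(counts$stage[bad], collapse = ", "),
         call. = FALSE)
  }
  if (nrow(counts) > 1) {
    chain <- utils::head(counts$kept, -1) != utils::tail(counts$input, -1)
    if (any(chain)) {
      stop("flowchart stages do not telescope after stage(s): ",
           paste(utils::head(counts$stage, -1)[chain], collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(counts)
}

#' Render a selection flowchart
#'
#' Validates the conservation invariants, appends a grand-total row
#' (`input` of the first stage, `kept` of the last, total exclusions) and
#' optionally writes CSV and JSON renditions.
#'
#' @param counts Flowchart tibble (see [run_selection()]).
#' @param csv_path,json_path Optional output paths.
#' @return The rendered tibble including the `total` row.
#' @export
render_flowchart <- function(counts, csv_path = NULL, json_path = NULL) {
  check_flowchart(counts)
  out <- counts
  if (nrow(counts) > 0) {
    total <- tibble::tibble(
      stage = "total",
      input = counts$input[1],
      kept = counts$kept[nrow(counts)],
      excluded = sum(counts$excluded))
    stopifnot(total$input == total$kept + total$excluded)
    out <- dplyr::bind_rows(counts, total)
  }
  if (!is.null(csv_path)) readr::write_csv(out, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, dataframe = "rows", auto_unbox = TRUE)
  }
  out
}

#' Share of records retained at one flowchart stage
#'
#' Convenience for headline figures such as "30% of all J01 prescriptions
#' carried an RTI or UTI indication": the percentage `kept / input` at a
#' named stage.
#'
#' @param counts Flowchart tibble.
#' @param stage Stage label.
#' @return Percentage (0-100).
#' @export
stage_share <- function(counts, stage) {
  i <- match(stage, counts$stage)
  if (is.na(i)) stop("no stage '", stage, "' in flowchart", call. = FALSE)
  100 * counts$kept[i] / counts$input[i]
}

#' Stacked-bar data for adherence figures
#'
#' Converts an adherence report into the per-sub-indication stacked shares
#' used in appropriateness figures: one row per displayed agent
#' combination with its category colour role (`A` green, `B` yellow, `C`
#' red, pooled rare combinations `other`, grey). Shares within a
#' sub-indication sum to 1. This is a pure re-arrangement of the report:
#' no quantity is re-computed.
#'
#' @param report An `adherence_report`.
#' @return Tibble with columns `sub_indication`, `combination`, `role`,
#'   `n`, `share`.
#' @export
render_adherence_figure_data <- function(report) {
  stopifnot(inherits(report, "adherence_report"))
  comb <- report$combinations
  tibble::tibble(
    sub_indication = comb$sub_indication,
    combination = comb$combination,
    role = comb$category,
    n = comb$n,
    share = comb$share)
}

#' Plot adherence figure data
#'
#' Optional cosmetic companion to [render_adherence_figure_data()]; the
#' data table is the contract, the plot is presentation.
#'
#' @param figure_data Output of [render_adherence_figure_data()].
#' @return A ggplot object.
#' @export
plot_adherence <- function(figure_data) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(figure_data,
                  ggplot2::aes(x = .data$sub_indication, y = .data$share,
                               fill = .data$role)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(A = "#2e7d32", B = "#f9a825",
                                          C = "#c62828", other = "#9e9e9e")) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "share of regimens",
                  fill = "guideline category") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

.md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Write an audit bundle
#'
#' Collects the outputs of one audit run -- flowchart, adherence
#' report(s), accuracy report -- into a directory with a manifest:
#' tool version, a digest of the selection parameters and guideline (so
#' any change in audit conditions changes the digest), the seed for
#' synthetic runs, and an md5 content digest per emitted file.
#' Re-running with identical inputs reproduces identical digests.
#'
#' @param dir Output directory.
#' @param flowchart Optional flowchart tibble.
#' @param adherence Optional `adherence_report` or named list of them.
#' @param accuracy Optional `accuracy_report`.
#' @param params Optional [selection_params()] included in the digest.
#' @param guideline Optional `guideline_table` included in the digest.
#' @param seed Optional seed recorded in the metadata.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_audit_bundle <- function(dir, flowchart = NULL, adherence = NULL,
                               accuracy = NULL, params = NULL,
                               guideline = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (!is.null(flowchart)) {
    p <- file.path(dir, "flowchart.csv")
    render_flowchart(flowchart, csv_path = p)
    files <- c(files, p)
  }
  if (!is.null(adherence)) {
    if (inherits(adherence, "adherence_report")) {
      adherence <- list(adherence = adherence)
    }
    for (nm in names(adherence)) {
      rep <- adherence[[nm]]
      p1 <- file.path(dir, paste0("adherence_", nm, ".csv"))
      readr::write_csv(rep$by_subindication, p1)
      p2 <- file.path(dir, paste0("combinations_", nm, ".csv"))
      readr::write_csv(rep$combinations, p2)
      files <- c(files, p1, p2)
    }
  }
  if (!is.null(accuracy)) {
    p <- file.path(dir, "accuracy_strata.csv")
    readr::write_csv(accuracy$strata, p)
    p2 <- file.path(dir, "accuracy_confusion.csv")
    readr::write_csv(accuracy$confusion, p2)
    files <- c(files, p, p2)
  }
  manifest <- list(
    tool = "stewardaudit",
    version = as.character(utils::packageVersion("stewardaudit")),
    seed = seed,
    params_digest = if (!is.null(params) || !is.null(guideline)) {
      .md5_of_object(list(params = unclass(params),
                          guideline = unclass(guideline)))
    },
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(digest = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
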