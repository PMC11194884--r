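# Ablation-grid definitions and the grid runner: 14 residual-attention
# subsets, 11 forward-fusion subsets, and 16 attention subsets on top of the
# full fusion cascade. The row sets are shipped as CSV data files so the
# structural coverage is auditable.

#' Load an ablation grid
#'
#' @param grid `"table3"` (attention subsets, no fusion), `"table4"` (fusion
#'   subsets, no attention), or `"table5"` (attention subsets over the full
#'   fusion cascade).
#' @return List of [ablation_config()] rows.
#' @export
ablation_grid <- function(grid = c("table3", "table4", "table5")) {
  grid <- match.arg(grid)
  path <- system.file("extdata", "grids", paste0(grid, ".csv"),
                      package = "affssd", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(attention_layers = "character",
                                fusion_layers = "character"))
  split_layers <- function(s) if (!nzchar(s)) character(0) else
    strsplit(s, ";", fixed = TRUE)[[1]]
  lapply(seq_len(nrow(df)), function(i)
    ablation_config(split_layers(df$attention_layers[i]),
                    split_layers(df$fusion_layers[i])))
}

#' Run an ablation grid
#'
#' Builds the detector for every row of the grid, trains it for `budget`
#' iterations on the manifest's training split, and (optionally) evaluates
#' mAP on the test split. One report row per configuration.
#'
#' @param grid A grid id (see [ablation_grid()]) or a list of
#'   [ablation_config()] objects.
#' @param manifest Dataset manifest.
#' @param budget Training iterations per row (>= 1).
#' @param config Base [train_config()]; `max_iterations` is overridden by
#'   `budget`.
#' @param input_size Backbone input size for the grid runs.
#' @param evaluate Also compute test-split mAP per row.
#' @return Data frame: `row`, `attention_layers`, `fusion_layers`,
#'   `parameters`, `final_loss`, `map`.
#' @export
run_ablation_grid <- function(grid, manifest, budget = 1L,
                              config = train_config(), input_size = 96L,
                              evaluate = FALSE) {
  if (budget < 1L) stop_config("budget must be >= 1")
  configs <- if (is.character(grid)) ablation_grid(grid) else grid
  config$max_iterations <- as.integer(budget)
  rows <- lapply(seq_along(configs), function(i) {
    ab <- configs[[i]]
    model <- build_affssd(backbone_config(input_size), ab,
                          num_classes = length(manifest$classes) + 1L)
    fit <- train_detector(model, manifest, config)
    data.frame(
      row = i,
      attention_layers = paste(ab$attention_layers, collapse = ";"),
      fusion_layers = paste(ab$fusion_layers, collapse = ";"),
      parameters = count_parameters(fit$model),
      final_loss = utils::tail(fit$curve$loss, 1),
      map = if (evaluate && length(manifest$test))
        evaluate_detector(fit$model, manifest)$map else NA_real_)
  })
  do.call(rbind, rows)
}
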