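# Greedy model soup: averages the weights of architecture-identical models,
# admitting members best-first only when the averaged weights do not worsen
# the ranking-data loss.

#' Greedy weight-averaging model soup
#'
#' Models are ranked by MSE on `ranking_data`; starting from the best, each
#' further model's weights are tentatively averaged in (uniformly over the
#' accepted members) and the averaged weights are kept only if they do not
#' worsen the ranking-data loss. By construction the soup is never worse
#' than the best single model on the ranking data.
#'
#' @param models List of trained `mrl_predictor` objects sharing one
#'   architecture.
#' @param ranking_data Library data.frame (`seq`, `mrl`) used for ranking
#'   and greedy acceptance. Use a held-out split that is not the final test
#'   set, so reported test performance stays unbiased.
#' @return An `mrl_predictor` with the souped weights; attribute `members`
#'   gives the indices (into `models`, ranked order) that were accepted,
#'   and attribute `ranking_loss` the soup's final ranking-data MSE.
#' @export
model_soup <- function(models, ranking_data) {
  if (length(models) == 0L) stop("no models to soup", call. = FALSE)
  cfgs <- lapply(models, function(m) unclass(m$cfg))
  if (length(unique(vapply(cfgs, function(cc) paste(unlist(cc),
                                                    collapse = "|"),
                           character(1L)))) != 1L) {
    stop("all soup members must share one architecture", call. = FALSE)
  }
  enc <- encode_library(ranking_data, models[[1L]]$cfg$input_len)
  losses <- vapply(models, function(m) {
    predictor_loss(m$params, m$cfg, enc$x, enc$y)
  }, numeric(1L))
  ord <- order(losses)
  soup <- models[[ord[1L]]]
  soup_params <- soup$params
  soup_loss <- losses[ord[1L]]
  members <- ord[1L]
  for (i in ord[-1L]) {
    k <- length(members)
    cand <- params_combine(soup_params, models[[i]]$params,
                           k / (k + 1), 1 / (k + 1))
    cand_loss <- predictor_loss(cand, soup$cfg, enc$x, enc$y)
    if (cand_loss <= soup_loss) {
      soup_params <- cand
      soup_loss <- cand_loss
      members <- c(members, i)
    }
  }
  soup$params <- soup_params
  soup$opt_state <- NULL
  structure(soup, members = members, ranking_loss = soup_loss)
}
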