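# Flattens a long-format panel dataset into the fully indexed representation
# consumed by the compiled likelihood core. All validation of the panel
# happens here: required columns, strictly increasing visit times, known
# codes, and dropping (with a warning) subjects observed only once.
panel_design <- function(data, params, space,
                         regime = c("partial", "complete"),
                         initial_split = c(R = 0, D0 = 1)) {
  regime <- match.arg(regime)
  need <- c("subject_id", "time", "state_code")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("Panel data must have columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("Panel data is empty.", call. = FALSE)
  covs <- param_covariates(params)
  miss <- setdiff(covs, names(data))
  if (length(miss)) {
    stop("Covariate column(s) missing from the data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  data <- dplyr::arrange(data, .data$subject_id, .data$time)
  codes <- as.character(data$state_code)
  bad <- !(codes %in% c("0", space$states))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("Unknown state code \"", codes[i], "\" (subject ",
         data$subject_id[i], ", row ", i, ").", call. = FALSE)
  }
  if (regime == "complete" && any(codes == "0")) {
    stop("regime = \"complete\" requires fully labelled states; ",
         "found code \"0\".", call. = FALSE)
  }

  ids <- data$subject_id
  runs <- rle(as.character(ids))
  n_obs <- runs$lengths
  ends <- cumsum(n_obs)
  starts <- ends - n_obs + 1L

  # strictly increasing times within subject
  dt_all <- diff(data$time)
  internal <- rep(TRUE, max(length(dt_all), 0L))
  if (length(dt_all)) internal[ends[-length(ends)]] <- FALSE
  if (any(dt_all[internal] <= 0)) {
    j <- which(internal & dt_all <= 0)[1L]
    stop("Visit times must be strictly increasing within subject ",
         ids[j], ".", call. = FALSE)
  }

  keep_subj <- n_obs >= 2L
  if (any(!keep_subj)) {
    warning(sum(!keep_subj), " subject(s) with a single visit dropped ",
            "(no likelihood contribution).", call. = FALSE)
    keep_rows <- rep(keep_subj, n_obs)
    data <- data[keep_rows, , drop = FALSE]
    codes <- codes[keep_rows]
    runs <- rle(as.character(data$subject_id))
    n_obs <- runs$lengths
    ends <- cumsum(n_obs)
    starts <- ends - n_obs + 1L
  }
  if (nrow(data) == 0L) stop("No subject has two or more visits.", call. = FALSE)

  ns <- length(space$states)
  ntot <- nrow(data)

  # per-visit weight rows over latent states
  masks <- matrix(0, ntot, ns)
  colnames(masks) <- space$states
  masks[cbind(which(codes != "0"), match(codes[codes != "0"], space$states))] <- 1
  zero <- codes == "0"
  masks[zero, "R"] <- 1
  masks[zero, "D0"] <- 1
  first <- starts[codes[starts] == "0"]
  if (length(first)) {
    masks[first, "R"] <- initial_split[[1]]
    masks[first, "D0"] <- initial_split[[2]]
  }

  # covariate profiles at interval left endpoints
  left <- unlist(lapply(seq_along(starts), function(i) {
    starts[i]:(ends[i] - 1L)
  }), use.names = FALSE)
  if (length(covs)) {
    zmat <- as.matrix(data[left, covs, drop = FALSE])
    storage.mode(zmat) <- "double"
    zkey <- do.call(paste, c(as.data.frame(zmat), sep = "\r"))
  } else {
    zmat <- matrix(numeric(0), nrow = length(left), ncol = 0)
    zkey <- rep("", length(left))
  }
  dts <- data$time[left + 1L] - data$time[left]
  pair_key <- paste(zkey, format(dts, digits = 17), sep = "\r|")
  upair <- !duplicated(pair_key)
  pair_of <- match(pair_key, pair_key[upair])
  uprof_key <- zkey[upair]
  uprof <- !duplicated(uprof_key)
  prof_of_pair <- match(uprof_key, uprof_key[uprof])
  profiles <- zmat[upair, , drop = FALSE][uprof, , drop = FALSE]

  # theta indexing
  labs <- transition_labels(space)
  ntr <- length(labs)
  beta_idx <- vector("list", ntr)
  beta_cov <- vector("list", ntr)
  at <- ntr
  for (k in seq_len(ntr)) {
    b <- params$beta[[labs[k]]]
    if (is.null(b)) {
      beta_idx[[k]] <- integer(0)
      beta_cov[[k]] <- integer(0)
    }
  }
  # coefficients are packed grouped by transition, in beta list order
  for (tr in names(params$beta)) {
    k <- match(tr, labs)
    nb <- length(params$beta[[tr]])
    beta_idx[[k]] <- as.integer(at + seq_len(nb) - 1L)
    beta_cov[[k]] <- as.integer(match(names(params$beta[[tr]]), covs) - 1L)
    at <- at + nb
  }

  list(
    n_states = as.integer(ns),
    trans_from = as.integer(match(space$transitions$from, space$states) - 1L),
    trans_to = as.integer(match(space$transitions$to, space$states) - 1L),
    lambda_idx = as.integer(seq_len(ntr) - 1L),
    beta_idx = beta_idx,
    beta_cov = beta_cov,
    profiles = profiles,
    pair_profile = as.integer(prof_of_pair - 1L),
    pair_dt = dts[upair],
    interval_pair = as.integer(pair_of - 1L),
    masks = masks,
    subj_obs_offset = as.integer(starts - 1L),
    subj_n_obs = as.integer(n_obs),
    subj_int_offset = as.integer(starts - seq_along(starts)),
    n_subjects = length(starts),
    n_observations = as.integer(ntot),
    term_map = param_map(params)
  )
}
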