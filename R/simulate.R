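#' Run one full value-chain simulation
#'
#' Integrates the whole stock-and-flow system by explicit forward
#' differences at the model's native half-day timestep, from the horizon
#' start to its end. A `scenario` (if supplied) switches on at the
#' configured scenario start date: extension-led recruitment, a Market-B
#' transport subsidy, cold storage, and external retail demand growth.
#' All stochastic inputs (produce quality, transport cost draws,
#' independent farmers' market split noise, household cost draws) are
#' pre-generated from `run_seed` in a fixed order, so a scenario run and
#' its do-nothing baseline with the same seed share common random numbers
#' and their outcome differences isolate the scenario effect.
#'
#' @param config configuration list, see [default_config()].
#' @param scenario `NULL` for the do-nothing baseline, or a list/row with
#'   `extension_rate`, `subsidy_B` (percent), `cs_active_raw`, `cs_level`,
#'   `demand_growth` (percent/year).
#' @param run_seed integer seed for this run's noise streams.
#' @param inputs fixture bundle from [make_fixture_inputs()]; built on the
#'   fly (seeded by `run_seed`) when omitted.
#' @param keep_series keep per-half-day output series (memory ~ a few MB).
#' @return An object of class `fvchain_run`: list with `outcomes`
#'   (`cum_purchases_B` kg/customer, `cum_profit_loop` Rs/farmer,
#'   `mean_roi`), `final` (end-of-horizon stocks), `diagnostics` (mass
#'   balance residuals, farmer-total deviation), and optionally `series`.
#' @export
run_simulation <- function(config = default_config(), scenario = NULL,
                           run_seed = 1L, inputs = NULL,
                           keep_series = FALSE) {
  if (is.null(inputs)) inputs <- make_fixture_inputs(config, seed = run_seed)
  cal <- inputs$calendar
  TT <- nrow(cal)
  t_s <- inputs$t_scenario
  t_sub_end <- inputs$t_subsidy_end

  # --- scenario switches -----------------------------------------------
  sc_ext <- 0; sc_sub <- 0; sc_growth <- 0
  cs_capA <- 0; cs_capB <- 0
  if (!is.null(scenario)) {
    thr <- config$scenario$cs_activation_threshold
    cs_on <- as.numeric(scenario[["cs_active_raw"]] >= thr)
    cs_capA <- cold_storage_capacity(cs_on, scenario[["cs_level"]], "A",
                                     config$scenario$cs_capacity_A,
                                     config$scenario$cs_capacity_B)
    cs_capB <- cold_storage_capacity(cs_on, scenario[["cs_level"]], "B",
                                     config$scenario$cs_capacity_A,
                                     config$scenario$cs_capacity_B)
    sc_ext <- scenario[["extension_rate"]]
    sc_sub <- scenario[["subsidy_B"]] / 100
    sc_growth <- scenario[["demand_growth"]] / 100
  }

  # --- unpack config ----------------------------------------------------
  ad <- config$adoption; pr <- config$production; mk <- config$marketing
  tr <- config$transport; td <- config$traders; dm <- config$demand
  M_total <- ad$total_farmers
  price_scale <- config$fixtures$price_level
  eta <- td$price_elasticity; pclamp <- td$price_clamp
  amb_shelf <- td$shelf_life; max_shelf <- td$shelf_life_cold
  margins <- td$margins; misc <- td$misc_cost; outb <- td$outbound_transport
  commA <- tr$commission_A; commB <- tr$commission_B

  # --- pre-generated noise (fixed order: common random numbers) --------
  set.seed(run_seed)
  q_lp <- stats::runif(TT, pr$quality_range[1], pr$quality_range[2])
  q_nl <- stats::runif(TT, pr$quality_range[1], pr$quality_range[2])
  u_loopA <- stats::runif(TT); u_loopB <- stats::runif(TT)
  u_selfA <- stats::runif(TT); u_selfB <- stats::runif(TT)
  u_split <- stats::runif(TT)
  cost_lp <- make_cost_draws(TT, config)
  cost_nl <- make_cost_draws(TT, config)

  tc_loopA <- tr$loop_A[1] + u_loopA * diff(tr$loop_A)
  tc_loopB <- tr$loop_B[1] + u_loopB * diff(tr$loop_B)
  tc_selfA <- tr$self_A[1] + u_selfA * diff(tr$self_A)
  tc_selfB <- tr$self_B[1] + u_selfB * diff(tr$self_B)

  # --- precomputed calendar series -------------------------------------
  morning <- cal$morning
  mf_lp <- cal$mf_loop; mf_nl <- cal$mf_nonloop
  season_start <- cal$season_start; year_start <- cal$year_start
  yields <- unname(pr$yields[cal$season])
  fv_base <- pr$fv_month_frac[cal$month]
  ref_price <- inputs$ref_price; staple <- inputs$staple_price

  sub_base <- ifelse(seq_len(TT) <= t_sub_end, tr$baseline_subsidy, 0)
  sub_A <- sub_base
  sub_B <- sub_base
  if (!is.null(scenario)) sub_B[t_s:TT] <- sc_sub
  growth <- rep(1, TT)
  if (sc_growth > 0) {
    idx <- t_s:TT
    growth[idx] <- (1 + sc_growth)^((idx - t_s + 1) / 730)
  }

  # --- state ------------------------------------------------------------
  L <- ad$initial_loop; NL <- M_total - L
  trust <- ad$trust_init
  pref_A <- mk$pref_A_init
  land <- c(lp = pr$land_loop, nl = pr$land_nonloop)
  ymult <- c(lp = 1, nl = 1)
  cumprof <- c(lp = 0, nl = 0)
  headroom <- c(lp = pr$yield_annual_cap, nl = pr$yield_annual_cap)
  D_A <- dm$reference_demand_A; D_B <- dm$reference_demand_B
  n_tr <- unname(td$counts) # A_dist, A_ws, A_ret, B_ws, B_ret
  Q <- matrix(0, nrow = max_shelf, ncol = 5)
  qpr_prev <- rep(ref_price[1], 5)

  # --- histories and running window sums -------------------------------
  W7 <- 14L; W30 <- 30L; W60 <- ad$trend_window
  h_lp_prof <- numeric(TT); h_nl_prof <- numeric(TT)
  h_lp_sf <- numeric(TT); h_nl_sf <- numeric(TT)
  h_sfA <- numeric(TT); h_sfB <- numeric(TT)
  h_mpA <- numeric(TT); h_mpB <- numeric(TT)
  h_tp <- matrix(0, nrow = 5, ncol = TT)
  h_coff <- matrix(0, nrow = 5, ncol = TT) # offered to cohort
  h_csold <- matrix(0, nrow = 5, ncol = TT) # bought by cohort
  s7 <- list(lp_prof = 0, nl_prof = 0, lp_sf = 0, nl_sf = 0,
             sfA = 0, sfB = 0, mpA = 0, mpB = 0)
  s7_coff <- numeric(5); s7_csold <- numeric(5)
  s30_lp_prof <- 0; s60_lp_prof <- 0
  s30_lp_sf <- 0; s60_lp_sf <- 0
  s60_tp <- numeric(5)
  # aggregation happens in the morning: the market-preference stock reacts
  # to the morning conditions members actually face, over the last week
  W7m <- 7L
  n_morn <- sum(morning)
  hm_sfA <- numeric(n_morn); hm_sfB <- numeric(n_morn)
  hm_mpA <- numeric(n_morn); hm_mpB <- numeric(n_morn)
  m_cnt <- 0L
  sm_sfA <- 0; sm_sfB <- 0; sm_mpA <- 0; sm_mpB <- 0

  # --- outcome accumulators and diagnostics ----------------------------
  cum_purch_B <- 0; cum_prof_lp <- 0
  roi_sum <- 0; roi_n <- 0L
  max_resid <- c(A = 0, B = 0)
  cap_dist <- td$capacity_distance; cap_ws <- td$capacity_wholesale
  custA <- dm$customers_A; custB <- dm$customers_B

  if (keep_series) {
    ser <- matrix(NA_real_, nrow = TT, ncol = 16)
    colnames(ser) <- c("loop_farmers", "trust", "pref_A", "loop_sold_A",
                       "loop_sold_B", "sold_A", "sold_B", "price_A",
                       "price_B", "cons_B_per_cust", "participation",
                       "stored_total", "sf_A", "sf_B", "mp_A", "mp_B")
  }

  eps <- 1e-12
  failed <- FALSE
  keep_lp <- 1 - pr$own_consumption_rate *
    (1 + pr$female_consumption_boost * pr$female_fraction_loop) -
    pr$giveaway_rate - pr$pre_farmgate_loss_rate
  keep_nl <- 1 - pr$own_consumption_rate *
    (1 + pr$female_consumption_boost * pr$female_fraction_nonloop) -
    pr$giveaway_rate - pr$pre_farmgate_loss_rate
  carried <- numeric(5) # running colSums(Q): inventory is usually empty
  zero5 <- numeric(5)
  entry_coeff <- td$entry_coeff; exit_coeff <- td$exit_coeff

  for (t in seq_len(TT)) {
    in_scen <- t >= t_s
    morn <- morning[t]

    # -- season-start reinvestment (first morning of each season) -------
    if (year_start[t]) headroom[] <- pr$yield_annual_cap
    if (season_start[t]) {
      for (pop in 1:2) {
        li <- invest_in_land(cumprof[pop], pr$land_price_per_katha,
                             pr$land_invest_rate, pr$land_invest_threshold,
                             pr$m2_per_katha)
        land[pop] <- land[pop] + li$area_bought
        cumprof[pop] <- cumprof[pop] - li$spend
        yi <- invest_in_yield(cumprof[pop], headroom[pop],
                              pr$yield_invest_rate, pr$yield_gain_per_rs)
        ymult[pop] <- ymult[pop] * (1 + yi$increment)
        headroom[pop] <- headroom[pop] - yi$increment
        cumprof[pop] <- cumprof[pop] - yi$spend
      }
    }

    # -- trailing weekly aggregates (history up to t-1) ------------------
    nw <- min(t - 1L, W7)
    if (nw > 0) {
      lp_prof7 <- s7$lp_prof / nw; nl_prof7 <- s7$nl_prof / nw
      lp_sf7 <- s7$lp_sf / nw; nl_sf7 <- s7$nl_sf / nw
      sfA7 <- s7$sfA / nw; sfB7 <- s7$sfB / nw
      mpA7 <- s7$mpA / nw; mpB7 <- s7$mpB / nw
      csf7 <- s7_csold / s7_coff
      csf7[!(s7_coff > eps)] <- 1
    } else {
      lp_prof7 <- nl_prof7 <- 0
      lp_sf7 <- nl_sf7 <- 0.9
      sfA7 <- sfB7 <- 0.9
      mpA7 <- mpB7 <- 0
      csf7 <- rep(1, 5)
    }

    # -- participation, land fraction, production -----------------------
    partic <- if (morn) {
      loop_participation_share(lp_prof7, nl_prof7, lp_sf7, nl_sf7,
                               mk$w_sales, mk$w_profit,
                               mk$participation_kappa,
                               mk$participation_share_min, mk$profit_scale)
    } else 0

    ratio <- ref_price[t] / staple[t]
    adj <- 0.8 + 0.4 * ratio / (ratio + pr$price_ratio_ref)
    frac <- min(fv_base[t] * adj, 1)

    prod_lp <- L * mf_lp[t] * land[1] * frac * yields[t] * ymult[1]
    prod_nl <- NL * mf_nl[t] * land[2] * frac * yields[t] * ymult[2]
    net_lp <- prod_lp * keep_lp
    net_nl <- prod_nl * keep_nl

    M_loop <- partic * net_lp # aggregated this morning
    M_nl <- net_nl + (1 - partic) * net_lp # independent channel

    # -- market split ----------------------------------------------------
    fA_l <- pref_A / 100
    fA_n <- min(max(mk$nonloop_base_A *
                      (1 + mk$nonloop_noise * (2 * u_split[t] - 1)), 0), 1)
    S_A_l <- M_loop * fA_l; S_B_l <- M_loop * (1 - fA_l)
    S_A_n <- M_nl * fA_n; S_B_n <- M_nl * (1 - fA_n)
    S_A <- S_A_l + S_A_n; S_B <- S_B_l + S_B_n

    h_A <- if (S_A > eps) (S_A_l * q_lp[t] + S_A_n * q_nl[t]) / S_A else q_nl[t]
    h_B <- if (S_B > eps) (S_B_l * q_lp[t] + S_B_n * q_nl[t]) / S_B else q_nl[t]
    qual <- c(h_A, h_A, h_A, h_B, h_B)

    # -- inventory ageing and spoilage ----------------------------------
    carried_in <- carried
    spoil <- zero5
    cs_share <- zero5
    if (in_scen && (cs_capA > 0 || cs_capB > 0)) {
      offA <- s7_coff[1:3]; offB <- s7_coff[4:5]
      shA <- if (sum(offA) > eps) offA / sum(offA) else rep(1 / 3, 3)
      shB <- if (sum(offB) > eps) offB / sum(offB) else rep(1 / 2, 2)
      cs_share <- c(cs_capA * shA, cs_capB * shB)
    }
    any_stock <- any(carried_in > eps)
    if (any_stock) {
      for (c_i in which(carried_in > eps)) {
        aged <- age_inventory(Q[, c_i], amb_shelf, cs_share[c_i])
        Q[, c_i] <- aged$queue
        spoil[c_i] <- aged$spoiled
      }
      carried <- colSums(Q)
      stored_old <- colSums(Q[(amb_shelf + 1):max_shelf, , drop = FALSE])
    } else {
      stored_old <- zero5
    }

    # -- trader capacities and allocation -------------------------------
    # external demand growth lifts downstream appetite market-wide:
    # wholesale and export demand directly, retail through its demand stock
    g_t <- growth[t]
    base_cap <- c(
      if (morn) n_tr[1] * cap_dist * g_t else 0,
      n_tr[2] * cap_ws * g_t,
      custA * D_A,
      n_tr[4] * cap_ws * g_t,
      custB * D_B
    )
    present <- c(morn, TRUE, TRUE, TRUE, TRUE)

    allocA <- trader_allocation(S_A, csf7[1:3], qpr_prev[1:3], present[1:3],
                                mk$w_sales, mk$w_profit, mk$alloc_kappa,
                                price_scale)
    allocB <- trader_allocation(S_B, csf7[4:5], qpr_prev[4:5], present[4:5],
                                mk$w_sales, mk$w_profit, mk$alloc_kappa,
                                price_scale)
    alloc <- c(allocA, allocB)

    # -- purchases: first-pass allocation, then intra-market spillover --
    dem_price <- base_cap - carried
    dem_price <- dem_price * (dem_price > 0)
    headroom_cs <- cs_share - stored_old
    headroom_cs <- headroom_cs * (headroom_cs > 0)
    buy_cap <- dem_price + headroom_cs
    buy <- alloc - (alloc - buy_cap) * (alloc > buy_cap)
    buy[!present] <- 0
    offered <- alloc
    # supply turned away by a full trader is offered to the others in the
    # same market while any capacity remains
    rc <- (buy_cap - buy) * present
    leftA <- S_A - (buy[1] + buy[2] + buy[3])
    rcA <- rc[1] + rc[2] + rc[3]
    if (leftA > eps && rcA > eps) {
      add <- if (leftA < rcA) leftA else rcA
      spl <- rc[1:3] * (add / rcA)
      buy[1:3] <- buy[1:3] + spl
      offered[1:3] <- offered[1:3] + spl
    }
    leftB <- S_B - (buy[4] + buy[5])
    rcB <- rc[4] + rc[5]
    if (leftB > eps && rcB > eps) {
      add <- if (leftB < rcB) leftB else rcB
      spl <- rc[4:5] * (add / rcB)
      buy[4:5] <- buy[4:5] + spl
      offered[4:5] <- offered[4:5] + spl
    }

    # -- price formation on the volumes each trader actually faces ------
    pratio <- (dem_price / offered)^eta
    pratio[offered <= eps] <- pclamp[2]
    pratio[dem_price <= eps & offered > eps] <- pclamp[1]
    pratio[pratio < pclamp[1]] <- pclamp[1]
    pratio[pratio > pclamp[2]] <- pclamp[2]
    pr_c <- ref_price[t] * pratio
    qpr <- pr_c * (qual + 0.5 * (1 - qual))

    # sales: carried (older) stock first, then today's fresh purchases
    stock_tot <- carried + buy
    sold_c <- stock_tot - (stock_tot - base_cap) * (stock_tot > base_cap)
    from_carried <- carried - (carried - sold_c) * (carried > sold_c)
    fresh_left <- buy - (sold_c - from_carried)
    if (any_stock && any(from_carried > eps)) {
      for (c_i in which(from_carried > eps)) {
        dr <- drain_inventory(Q[, c_i], from_carried[c_i])
        Q[, c_i] <- dr$queue
      }
    }
    if (any(fresh_left > eps)) Q[1, ] <- Q[1, ] + fresh_left
    carried_out <- carried - from_carried + fresh_left
    carried <- carried_out
    stored_end <- if (any_stock || any(fresh_left > eps)) {
      colSums(Q[(amb_shelf + 1):max_shelf, , drop = FALSE])
    } else {
      zero5
    }

    # mass balance residual per market
    rA <- sum(carried_in[1:3]) + sum(buy[1:3]) -
      (sum(sold_c[1:3]) + sum(spoil[1:3]) + sum(carried_out[1:3]))
    rB <- sum(carried_in[4:5]) + sum(buy[4:5]) -
      (sum(sold_c[4:5]) + sum(spoil[4:5]) + sum(carried_out[4:5]))
    max_resid[1] <- max(max_resid[1], abs(rA))
    max_resid[2] <- max(max_resid[2], abs(rB))

    # -- trader profits and entry/exit ----------------------------------
    sell_price <- qpr * (1 + margins)
    rent <- td$storage_rent * stored_end
    costs_c <- misc * n_tr + rent + outb * sold_c
    tp <- sold_c * sell_price - buy * qpr - costs_c
    s60_tp <- s60_tp + tp
    h_tp[, t] <- tp
    if (t > W60) s60_tp <- s60_tp - h_tp[, t - W60]
    n_tr <- n_tr + entry_coeff * s60_tp * (s60_tp > 0) -
      exit_coeff * n_tr * (s60_tp < 0)
    n_tr <- n_tr * (n_tr > 0)

    # -- farmer accounting ----------------------------------------------
    buyA <- sum(buy[1:3]); buyB <- sum(buy[4:5])
    sfA <- if (S_A > eps) buyA / S_A else sfA7
    sfB <- if (S_B > eps) buyB / S_B else sfB7
    avg_pA <- if (buyA > eps) sum(buy[1:3] * qpr[1:3]) / buyA else qpr[2]
    avg_pB <- if (buyB > eps) sum(buy[4:5] * qpr[4:5]) / buyB else qpr[4]

    fee_A <- tc_loopA[t] * (1 - sub_A[t])
    fee_B <- tc_loopB[t] * (1 - sub_B[t])

    rev_lp <- S_A_l * sfA * avg_pA * (1 - commA) +
      S_B_l * sfB * avg_pB * (1 - commB)
    mcost_lp <- S_A_l * fee_A + S_B_l * fee_B
    # the independent channel carries true non-members plus members who
    # skipped aggregation today; revenue follows the produce's owners
    self_lp <- (1 - partic) * net_lp
    phi <- if (M_nl > eps) self_lp / M_nl else 0
    rev_ind <- S_A_n * sfA * avg_pA * (1 - commA) +
      S_B_n * sfB * avg_pB * (1 - commB)
    mcost_ind <- S_A_n * tc_selfA[t] + S_B_n * tc_selfB[t]
    net_ind <- rev_ind - mcost_ind

    lp_prof_t <- (rev_lp - mcost_lp + phi * net_ind) / max(L, 1) - cost_lp[t]
    nl_prof_t <- ((1 - phi) * net_ind) / max(NL, 1) - cost_nl[t]
    cumprof[1] <- cumprof[1] + lp_prof_t
    cumprof[2] <- cumprof[2] + nl_prof_t

    ind_sold <- S_A_n * sfA + S_B_n * sfB
    lp_sup <- M_loop + self_lp
    lp_sf_t <- if (lp_sup > eps) {
      (S_A_l * sfA + S_B_l * sfB + phi * ind_sold) / lp_sup
    } else lp_sf7
    nl_sf_t <- if (net_nl > eps) ((1 - phi) * ind_sold) / net_nl else nl_sf7
    mpA_t <- sfA * avg_pA * (1 - commA) - fee_A
    mpB_t <- sfB * avg_pB * (1 - commB) - fee_B

    # -- preference, trust, adoption ------------------------------------
    if (morn) {
      m_cnt <- m_cnt + 1L
      hm_sfA[m_cnt] <- sfA; hm_sfB[m_cnt] <- sfB
      hm_mpA[m_cnt] <- mpA_t; hm_mpB[m_cnt] <- mpB_t
      sm_sfA <- sm_sfA + sfA; sm_sfB <- sm_sfB + sfB
      sm_mpA <- sm_mpA + mpA_t; sm_mpB <- sm_mpB + mpB_t
      if (m_cnt > W7m) {
        mm <- m_cnt - W7m
        sm_sfA <- sm_sfA - hm_sfA[mm]; sm_sfB <- sm_sfB - hm_sfB[mm]
        sm_mpA <- sm_mpA - hm_mpA[mm]; sm_mpB <- sm_mpB - hm_mpB[mm]
      }
      nm <- min(m_cnt, W7m)
      pref_A <- update_market_preference(pref_A, sm_mpA / nm, sm_mpB / nm,
                                         sm_sfA / nm, sm_sfB / nm,
                                         mk$pref_adjustment_rate, mk$w_sales,
                                         mk$w_profit, price_scale)
    }

    util <- loop_utility(lp_prof7, nl_prof7, lp_sf7, nl_sf7,
                         ad$w_profit, ad$w_sales)
    if (t > W60) {
      prof_tr <- trend_sign(s30_lp_prof / W30, (s60_lp_prof - s30_lp_prof) / W30,
                            ad$trend_deadband)
      sf_tr <- trend_sign(s30_lp_sf / W30, (s60_lp_sf - s30_lp_sf) / W30,
                          ad$trend_deadband)
      trust <- update_trust(trust, prof_tr, sf_tr,
                            ad$trust_gain, ad$trust_decay)
    }
    p_eff <- if (in_scen) sc_ext else ad$extension_rate
    fl <- adoption_flow(L, NL, trust, util, p_eff, ad$imitation_coeff,
                        ad$disadoption_rate, M_total, ad$disadoption_mode)
    L <- L + fl$adoptions - fl$disadoptions
    NL <- M_total - L

    # -- retail demand ---------------------------------------------------
    retail_pA <- qpr[3] * (1 + margins[3])
    retail_pB <- qpr[5] * (1 + margins[5])
    tgt_A <- target_demand(retail_pA, dm$reference_retail_price_A,
                           dm$reference_demand_A, dm$elasticity_urban) *
      growth[t]
    tgt_B <- target_demand(retail_pB, dm$reference_retail_price_B,
                           dm$reference_demand_B, dm$elasticity_rural) *
      growth[t]
    D_A <- smooth_demand(D_A, tgt_A, dm$smoothing_halfdays)
    D_B <- smooth_demand(D_B, tgt_B, dm$smoothing_halfdays)

    # -- outcome accumulation -------------------------------------------
    cons_B_per_cust <- sold_c[5] / custB
    if (in_scen) {
      cum_purch_B <- cum_purch_B + cons_B_per_cust
      cum_prof_lp <- cum_prof_lp + lp_prof_t
      fees_t <- S_A_l * fee_A + S_B_l * fee_B
      kg_sold_lp <- S_A_l * sfA + S_B_l * sfB
      if (kg_sold_lp > eps) {
        roi_sum <- roi_sum + fees_t / (config$roi$compensation_rate * kg_sold_lp)
        roi_n <- roi_n + 1L
      }
    }

    # -- record histories and update window sums ------------------------
    h_lp_prof[t] <- lp_prof_t; h_nl_prof[t] <- nl_prof_t
    h_lp_sf[t] <- lp_sf_t; h_nl_sf[t] <- nl_sf_t
    h_sfA[t] <- sfA; h_sfB[t] <- sfB
    h_mpA[t] <- mpA_t; h_mpB[t] <- mpB_t
    h_coff[, t] <- offered; h_csold[, t] <- buy

    s7$lp_prof <- s7$lp_prof + lp_prof_t; s7$nl_prof <- s7$nl_prof + nl_prof_t
    s7$lp_sf <- s7$lp_sf + lp_sf_t; s7$nl_sf <- s7$nl_sf + nl_sf_t
    s7$sfA <- s7$sfA + sfA; s7$sfB <- s7$sfB + sfB
    s7$mpA <- s7$mpA + mpA_t; s7$mpB <- s7$mpB + mpB_t
    s7_coff <- s7_coff + alloc; s7_csold <- s7_csold + buy
    if (t > W7) {
      tm <- t - W7
      s7$lp_prof <- s7$lp_prof - h_lp_prof[tm]
      s7$nl_prof <- s7$nl_prof - h_nl_prof[tm]
      s7$lp_sf <- s7$lp_sf - h_lp_sf[tm]
      s7$nl_sf <- s7$nl_sf - h_nl_sf[tm]
      s7$sfA <- s7$sfA - h_sfA[tm]; s7$sfB <- s7$sfB - h_sfB[tm]
      s7$mpA <- s7$mpA - h_mpA[tm]; s7$mpB <- s7$mpB - h_mpB[tm]
      s7_coff <- s7_coff - h_coff[, tm]; s7_csold <- s7_csold - h_csold[, tm]
    }
    s30_lp_prof <- s30_lp_prof + lp_prof_t
    s60_lp_prof <- s60_lp_prof + lp_prof_t
    s30_lp_sf <- s30_lp_sf + lp_sf_t
    s60_lp_sf <- s60_lp_sf + lp_sf_t
    if (t > W30) {
      s30_lp_prof <- s30_lp_prof - h_lp_prof[t - W30]
      s30_lp_sf <- s30_lp_sf - h_lp_sf[t - W30]
    }
    if (t > W60) {
      s60_lp_prof <- s60_lp_prof - h_lp_prof[t - W60]
      s60_lp_sf <- s60_lp_sf - h_lp_sf[t - W60]
    }

    qpr_prev <- qpr

    if (keep_series) {
      ser[t, ] <- c(L, trust, pref_A, S_A_l * sfA, S_B_l * sfB,
                    sum(sold_c[1:3]), sum(sold_c[4:5]), avg_pA, avg_pB,
                    cons_B_per_cust, partic, sum(carried_out),
                    sfA, sfB, mpA_t, mpB_t)
    }

    if (!is.finite(L) || !is.finite(cumprof[1]) || !is.finite(D_B)) {
      failed <- TRUE
      break
    }
  }

  mean_roi <- if (roi_n > 0) roi_sum / roi_n else NA_real_
  out <- list(
    outcomes = list(
      cum_purchases_B = cum_purch_B,
      cum_profit_loop = cum_prof_lp,
      mean_roi = mean_roi
    ),
    final = list(
      loop_farmers = L, nonloop_farmers = NL, trust = trust,
      pref_A = pref_A, trader_counts = stats::setNames(n_tr, names(td$counts)),
      cumulative_profit = cumprof, land = land, yield_multiplier = ymult
    ),
    diagnostics = list(
      max_mass_residual = max_resid,
      farmer_total_deviation = abs(L + NL - M_total),
      failed = failed
    ),
    run_seed = run_seed
  )
  if (keep_series) {
    out$series <- data.frame(index = cal$index, date = cal$date,
                             day = cal$day, morning = cal$morning, ser)
  }
  class(out) <- "fvchain_run"
  out
}

#' @export
print.fvchain_run <- function(x, ...) {
  cat("<fvchain_run> seed", x$run_seed,
      if (x$diagnostics$failed) "(FAILED)" else "", "\n")
  cat(sprintf("  cumulative Market-B purchases: %.2f kg/customer\n",
              x$outcomes$cum_purchases_B))
  cat(sprintf("  cumulative member profit:      %.0f Rs/farmer\n",
              x$outcomes$cum_profit_loop))
  cat(sprintf("  mean scheme ROI:               %.2f\n", x$outcomes$mean_roi))
  cat(sprintf("  final members: %.0f of %.0f farmers; trust %.2f; pref A %.0f%%\n",
              x$final$loop_farmers,
              x$final$loop_farmers + x$final$nonloop_farmers,
              x$final$trust, x$final$pref_A))
  invisible(x)
}

#' Daily aggregation of a half-day series
#'
#' @param series per-half-day `series` data.frame from [run_simulation()].
#' @param column column to aggregate.
#' @param fun aggregation function (sum for quantities).
#' @return data.frame with `timestep` (day number) and `value`.
#' @export
daily_series <- function(series, column, fun = sum) {
  agg <- tapply(series[[column]], series$day, fun)
  data.frame(timestep = as.integer(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}
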