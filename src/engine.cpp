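#include <Rcpp.h>
using namespace Rcpp;

// Disk containment with minimum-image convention so droplets may straddle a
// periodic boundary. Boundary points (d == r) count as condensed.
static inline bool in_disks(double x, double y, const double* cx,
                            const double* cy, const double* r2, int nd,
                            double bw, double bh, bool periodic) {
  for (int k = 0; k < nd; ++k) {
    double dx = x - cx[k], dy = y - cy[k];
    if (periodic) {
      if (dx > 0.5 * bw) dx -= bw; else if (dx < -0.5 * bw) dx += bw;
      if (dy > 0.5 * bh) dy -= bh; else if (dy < -0.5 * bh) dy += bh;
    }
    if (dx * dx + dy * dy <= r2[k]) return true;
  }
  return false;
}

// Marsaglia polar normal draws from R's uniform stream (seeded by
// set.seed); ~2-3x faster than the default inversion sampler in the
// particle loops, still fully reproducible from the R seed.
static double spare_norm;
static bool have_spare = false;
static inline double fast_norm() {
  if (have_spare) {
    have_spare = false;
    return spare_norm;
  }
  double u, v, s;
  do {
    u = 2.0 * unif_rand() - 1.0;
    v = 2.0 * unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  const double f = std::sqrt(-2.0 * std::log(s) / s);
  spare_norm = v * f;
  have_spare = true;
  return u * f;
}

static inline double wrap1(double v, double L) {
  // floor-based wrap (avoids fmod) -> result in [0, L)
  v -= L * std::floor(v / L);
  if (v >= L) v = 0.0;
  return v;
}

// Shared particle stepper for the equilibrium two-phase simulator and the
// in-silico FRAP assay. Molecules carry a binary motion state (0 = confined,
// 1 = mobile). The diffusion coefficient for a whole dt-step is that of the
// region at the step's start, even when the step crosses a phase boundary.
// State switching is evaluated once per dt for molecules inside condensed
// regions; molecules in the dilute phase are always mobile.
//
// rois / bleached are optional (0-row matrices disable them): bleached[i, j]
// flags molecule i as photo-bleached with respect to ROI j; per record the
// unbleached count inside each ROI is stored.
// [[Rcpp::export]]
List particle_sim_cpp(NumericVector x0, NumericVector y0, IntegerVector state0,
                      double box_w, double box_h, NumericMatrix disks,
                      double D_d, double D_m, double D_c, double P_cm,
                      double P_mc, double dt, int n_steps, int record_every,
                      NumericMatrix rois, LogicalMatrix bleached) {
  have_spare = false;
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<int> state(state0.begin(), state0.end());

  const int nd = disks.nrow();
  std::vector<double> cx(nd), cy(nd), r2(nd);
  double area_c = 0.0;
  for (int k = 0; k < nd; ++k) {
    cx[k] = disks(k, 0);
    cy[k] = disks(k, 1);
    r2[k] = disks(k, 2) * disks(k, 2);
    area_c += M_PI * r2[k];
  }

  const int nroi = rois.nrow();
  std::vector<double> rx(nroi), ry(nroi), rr2(nroi);
  for (int j = 0; j < nroi; ++j) {
    rx[j] = rois(j, 0);
    ry[j] = rois(j, 1);
    rr2[j] = rois(j, 2) * rois(j, 2);
  }

  const double sd_d = std::sqrt(2.0 * D_d * dt);
  const double sd_m = std::sqrt(2.0 * D_m * dt);
  const double sd_c = std::sqrt(2.0 * D_c * dt);

  // tri-state containment grid (0 outside, 1 inside, 2 near a boundary):
  // one lookup replaces the disk loop except within half a cell diagonal
  // of a boundary, where the exact test runs
  const double gcell = 0.05;
  const int gnx = std::max(1, (int)std::ceil(box_w / gcell));
  const int gny = std::max(1, (int)std::ceil(box_h / gcell));
  std::vector<unsigned char> grid((size_t)gnx * gny);
  const double margin = gcell * 0.7071067811865476;
  for (int gj = 0; gj < gny; ++gj) {
    for (int gi = 0; gi < gnx; ++gi) {
      const double gx = (gi + 0.5) * gcell, gy = (gj + 0.5) * gcell;
      double dmin = 1e30;  // signed distance to the nearest disk edge
      for (int k = 0; k < nd; ++k) {
        double dx = gx - cx[k], dy = gy - cy[k];
        if (dx > 0.5 * box_w) dx -= box_w; else if (dx < -0.5 * box_w) dx += box_w;
        if (dy > 0.5 * box_h) dy -= box_h; else if (dy < -0.5 * box_h) dy += box_h;
        const double d = std::sqrt(dx * dx + dy * dy) - std::sqrt(r2[k]);
        if (d < dmin) dmin = d;
      }
      grid[(size_t)gj * gnx + gi] =
          (std::abs(dmin) <= margin) ? 2 : (dmin < 0 ? 1 : 0);
    }
  }
  auto is_cond = [&](double x, double y) -> bool {
    int gi = (int)(x / gcell), gj = (int)(y / gcell);
    if (gi >= gnx) gi = gnx - 1;
    if (gj >= gny) gj = gny - 1;
    const unsigned char g = grid[(size_t)gj * gnx + gi];
    if (g != 2) return g == 1;
    return in_disks(x, y, cx.data(), cy.data(), r2.data(), nd, box_w, box_h,
                    true);
  };

  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec);
  IntegerVector rec_nc(n_rec);
  IntegerMatrix rec_roi(n_rec, nroi);
  IntegerMatrix rec_roi_tot(n_rec, nroi);

  int irec = 0;
  auto record = [&](int step) {
    rec_t[irec] = step * dt;
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (is_cond(x[i], y[i])) ++nc;
    rec_nc[irec] = nc;
    for (int j = 0; j < nroi; ++j) {
      int cnt = 0, tot = 0;
      for (int i = 0; i < n; ++i) {
        double dx = x[i] - rx[j], dy = y[i] - ry[j];
        if (dx * dx + dy * dy <= rr2[j]) {
          ++tot;
          if (!bleached(i, j)) ++cnt;
        }
      }
      rec_roi(irec, j) = cnt;
      rec_roi_tot(irec, j) = tot;
    }
    ++irec;
  };

  // Confined dwells are sampled as geometric step counts (identical in law
  // to per-step Bernoulli switching at P_cm) so stationary molecules cost
  // no random draws while they sit.
  const long CONF_FOREVER = std::numeric_limits<long>::max();
  auto draw_dwell = [&]() -> long {
    if (P_cm <= 0) return CONF_FOREVER;
    const double u = unif_rand();
    const double k = std::floor(std::log(u) / std::log(1.0 - P_cm));
    return (k > 1e18) ? CONF_FOREVER : (long)k;
  };
  std::vector<long> conf_left(n, 0);
  for (int i = 0; i < n; ++i)
    if (state[i] == 0) conf_left[i] = draw_dwell();

  record(0);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      int s = state[i];
      if (s == 0) {
        // confined molecules do not move (D_c = 0 path): region unchanged
        if (sd_c <= 0) {
          if (conf_left[i] > 0) {
            --conf_left[i];
            continue;
          }
          state[i] = 1;
          x[i] = wrap1(x[i] + sd_m * fast_norm(), box_w);
          y[i] = wrap1(y[i] + sd_m * fast_norm(), box_h);
          continue;
        }
        // slowly diffusing confined state: region can change, fall back to
        // the per-step rule
        const bool cond = is_cond(x[i], y[i]);
        if (!cond) {
          s = 1;
        } else if (conf_left[i] > 0) {
          --conf_left[i];
        } else {
          s = 1;
        }
        state[i] = s;
        const double sd = (s == 0) ? sd_c : (cond ? sd_m : sd_d);
        if (sd > 0) {
          x[i] = wrap1(x[i] + sd * fast_norm(), box_w);
          y[i] = wrap1(y[i] + sd * fast_norm(), box_h);
        }
      } else {
        const bool cond = is_cond(x[i], y[i]);
        if (cond && P_mc > 0 && unif_rand() < P_mc) {
          state[i] = 0;
          conf_left[i] = draw_dwell();
          if (sd_c > 0) {
            x[i] = wrap1(x[i] + sd_c * fast_norm(), box_w);
            y[i] = wrap1(y[i] + sd_c * fast_norm(), box_h);
          }
          continue;
        }
        const double sd = cond ? sd_m : sd_d;
        if (sd > 0) {
          x[i] = wrap1(x[i] + sd * fast_norm(), box_w);
          y[i] = wrap1(y[i] + sd * fast_norm(), box_h);
        }
      }
    }
    if (step % record_every == 0) record(step);
  }

  return List::create(
      _["t"] = rec_t, _["n_condensed"] = rec_nc, _["roi_unbleached"] = rec_roi,
      _["roi_total"] = rec_roi_tot, _["area_condensed"] = area_c,
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["state"] = IntegerVector(state.begin(), state.end()));
}

// Propagate condensate-scene tracks: state switching once per frame, motion
// integrated in n_sub sub-steps per frame with the diffusion coefficient of
// the region at each sub-step's start (condensed mobile D_m, dilute D_d).
// Confined frames either anchor the molecule and scatter the emitted
// localization by the PSF scale (psf_mode) or diffuse slowly with D_c.
// [[Rcpp::export]]
List propagate_scene_cpp(NumericVector x0, NumericVector y0,
                         IntegerVector state0, IntegerVector lens,
                         NumericMatrix disks, double D_d, double D_m,
                         double D_c, double P_cm, double P_mc, double tfr,
                         int n_sub, bool psf_mode, double psf_s) {
  have_spare = false;
  const int ntr = x0.size();
  const int nd = disks.nrow();
  std::vector<double> cx(nd), cy(nd), r2(nd);
  for (int k = 0; k < nd; ++k) {
    cx[k] = disks(k, 0);
    cy[k] = disks(k, 1);
    r2[k] = disks(k, 2) * disks(k, 2);
  }
  const double dt_sub = tfr / n_sub;
  const double sd_d = std::sqrt(2.0 * D_d * dt_sub);
  const double sd_m = std::sqrt(2.0 * D_m * dt_sub);
  const double sd_c = std::sqrt(2.0 * D_c * dt_sub);
  long total = 0;
  for (int i = 0; i < ntr; ++i) total += lens[i];
  NumericVector lx(total), ly(total);
  IntegerVector cond_out(total), state_out(total);
  // huge box so in_disks never wraps
  const double BIG = 1e9;
  long off = 0;
  for (int i = 0; i < ntr; ++i) {
    double px = x0[i], py = y0[i];
    int s = state0[i];
    for (int t = 0; t < lens[i]; ++t) {
      if (t > 0) {
        const bool cond = in_disks(px, py, cx.data(), cy.data(), r2.data(),
                                   nd, BIG, BIG, false);
        if (!cond) {
          s = 1;
        } else if (s == 0) {
          if (P_cm > 0 && unif_rand() < P_cm) s = 1;
        } else {
          if (P_mc > 0 && unif_rand() < P_mc) s = 0;
        }
        if (s == 1) {
          for (int k = 0; k < n_sub; ++k) {
            const bool c2 = in_disks(px, py, cx.data(), cy.data(), r2.data(),
                                     nd, BIG, BIG, false);
            const double sd = c2 ? sd_m : sd_d;
            px += sd * fast_norm();
            py += sd * fast_norm();
          }
        } else if (!psf_mode && sd_c > 0) {
          for (int k = 0; k < n_sub; ++k) {
            px += sd_c * fast_norm();
            py += sd_c * fast_norm();
          }
        }
      }
      if (s == 0 && psf_mode) {
        lx[off + t] = px + psf_s * norm_rand();
        ly[off + t] = py + psf_s * norm_rand();
      } else {
        lx[off + t] = px;
        ly[off + t] = py;
      }
      cond_out[off + t] = in_disks(px, py, cx.data(), cy.data(), r2.data(),
                                   nd, BIG, BIG, false) ? 1 : 0;
      state_out[off + t] = s;
    }
    off += lens[i];
  }
  return List::create(_["x"] = lx, _["y"] = ly, _["condensed"] = cond_out,
                      _["state"] = state_out);
}

// Exact neighbour counts within Euclidean radius (self-inclusive), via a
// cell list with cell edge = radius.
// [[Rcpp::export]]
IntegerVector count_neighbors_cpp(NumericVector x, NumericVector y,
                                  double radius) {
  const int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  double xmin = x[0], ymin = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (y[i] < ymin) ymin = y[i];
  }
  const double cell = radius;
  std::vector<int> ix(n), iy(n);
  int nx = 1, ny = 1;
  for (int i = 0; i < n; ++i) {
    ix[i] = (int)std::floor((x[i] - xmin) / cell);
    iy[i] = (int)std::floor((y[i] - ymin) / cell);
    if (ix[i] + 1 > nx) nx = ix[i] + 1;
    if (iy[i] + 1 > ny) ny = iy[i] + 1;
  }
  std::vector<std::vector<int> > bins((size_t)nx * ny);
  for (int i = 0; i < n; ++i) bins[(size_t)iy[i] * nx + ix[i]].push_back(i);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      const int cy = iy[i] + dy;
      if (cy < 0 || cy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        const int cxi = ix[i] + dx;
        if (cxi < 0 || cxi >= nx) continue;
        const std::vector<int>& b = bins[(size_t)cy * nx + cxi];
        for (size_t k = 0; k < b.size(); ++k) {
          const int j = b[k];
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}

// Even-odd rule point-in-polygon test (single ring).
// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      if (((vy[j] > py[i]) != (vy[k] > py[i])) &&
          (px[i] < (vx[k] - vx[j]) * (py[i] - vy[j]) / (vy[k] - vy[j]) + vx[j]))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}

// One scaled forward-backward sweep over a pooled set of tracks for the
// two-state (general K-state) displacement HMM with 2D Brownian emission
// b_k(d) = d/(2 D_k t) exp(-d^2 / (4 D_k t)). Returns the sufficient
// statistics for the Baum-Welch M-step plus the total log-likelihood.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericVector d, IntegerVector lens, NumericVector D,
                   NumericMatrix A, NumericVector pi0, double tfr) {
  const int K = D.size();
  const int ntr = lens.size();
  std::vector<double> c4(K), c2(K);
  for (int k = 0; k < K; ++k) {
    c4[k] = 4.0 * D[k] * tfr;
    c2[k] = 2.0 * D[k] * tfr;
  }
  double loglik = 0.0;
  NumericVector gamma1(K), gamma_sum(K), gamma_d2(K);
  NumericMatrix xi(K, K);

  int off = 0;
  std::vector<double> b, alpha, beta, ct;
  for (int tr = 0; tr < ntr; ++tr) {
    const int T = lens[tr];
    b.assign((size_t)T * K, 0.0);
    alpha.assign((size_t)T * K, 0.0);
    beta.assign((size_t)T * K, 0.0);
    ct.assign(T, 0.0);
    for (int t = 0; t < T; ++t) {
      const double dt_ = d[off + t];
      for (int k = 0; k < K; ++k) {
        double e = (dt_ / c2[k]) * std::exp(-dt_ * dt_ / c4[k]);
        if (e < 1e-300 || !std::isfinite(e)) e = 1e-300;
        b[(size_t)t * K + k] = e;
      }
    }
    // forward
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = pi0[k] * b[k];
      c0 += alpha[k];
    }
    ct[0] = c0;
    for (int k = 0; k < K; ++k) alpha[k] /= c0;
    for (int t = 1; t < T; ++t) {
      double cs = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j)
          s += alpha[(size_t)(t - 1) * K + j] * A(j, k);
        const double v = s * b[(size_t)t * K + k];
        alpha[(size_t)t * K + k] = v;
        cs += v;
      }
      ct[t] = cs;
      for (int k = 0; k < K; ++k) alpha[(size_t)t * K + k] /= cs;
    }
    // backward
    for (int k = 0; k < K; ++k) beta[(size_t)(T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k)
          s += A(j, k) * b[(size_t)(t + 1) * K + k] *
               beta[(size_t)(t + 1) * K + k];
        beta[(size_t)t * K + j] = s / ct[t + 1];
      }
    }
    // accumulate
    for (int t = 0; t < T; ++t) {
      loglik += std::log(ct[t]);
      const double d2 = d[off + t] * d[off + t];
      for (int k = 0; k < K; ++k) {
        const double g = alpha[(size_t)t * K + k] * beta[(size_t)t * K + k];
        if (t == 0) gamma1[k] += g;
        gamma_sum[k] += g;
        gamma_d2[k] += g * d2;
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      for (int j = 0; j < K; ++j) {
        for (int k = 0; k < K; ++k) {
          xi(j, k) += alpha[(size_t)t * K + j] * A(j, k) *
                      b[(size_t)(t + 1) * K + k] *
                      beta[(size_t)(t + 1) * K + k] / ct[t + 1];
        }
      }
    }
    off += T;
  }
  return List::create(_["loglik"] = loglik, _["gamma1"] = gamma1,
                      _["gamma_sum"] = gamma_sum, _["gamma_d2"] = gamma_d2,
                      _["xi"] = xi, _["n_tracks"] = ntr);
}

// Viterbi decoding for per-step state labels under the fitted model.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector d, IntegerVector lens,
                              NumericVector D, NumericMatrix A,
                              NumericVector pi0, double tfr) {
  const int K = D.size();
  const int ntr = lens.size();
  IntegerVector path(d.size());
  std::vector<double> lA((size_t)K * K), lpi(K);
  for (int j = 0; j < K; ++j) {
    lpi[j] = std::log(std::max(pi0[j], 1e-300));
    for (int k = 0; k < K; ++k)
      lA[(size_t)j * K + k] = std::log(std::max(A(j, k), 1e-300));
  }
  int off = 0;
  for (int tr = 0; tr < ntr; ++tr) {
    const int T = lens[tr];
    std::vector<double> delta((size_t)T * K);
    std::vector<int> psi((size_t)T * K);
    for (int t = 0; t < T; ++t) {
      const double dt_ = std::max(d[off + t], 1e-12);
      for (int k = 0; k < K; ++k) {
        const double lb = std::log(dt_ / (2.0 * D[k] * tfr)) -
                          dt_ * dt_ / (4.0 * D[k] * tfr);
        if (t == 0) {
          delta[k] = lpi[k] + lb;
          psi[k] = 0;
        } else {
          double best = -INFINITY;
          int arg = 0;
          for (int j = 0; j < K; ++j) {
            const double v = delta[(size_t)(t - 1) * K + j] + lA[(size_t)j * K + k];
            if (v > best) { best = v; arg = j; }
          }
          delta[(size_t)t * K + k] = best + lb;
          psi[(size_t)t * K + k] = arg;
        }
      }
    }
    int s = 0;
    double best = -INFINITY;
    for (int k = 0; k < K; ++k)
      if (delta[(size_t)(T - 1) * K + k] > best) {
        best = delta[(size_t)(T - 1) * K + k];
        s = k;
      }
    path[off + T - 1] = s;
    for (int t = T - 2; t >= 0; --t) {
      s = psi[(size_t)(t + 1) * K + s];
      path[off + t] = s;
    }
    off += T;
  }
  return path;
}
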