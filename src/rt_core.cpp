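// Discrete-time core of the 1D non-Markovian run-and-tumble walker.
//
// Each time step of duration dt the walker either translates by v*dt in its
// current direction or sits in a tumble phase.  After translating (and
// reflecting off the box walls) it appends the local concentration to its
// history ring buffer, evaluates the memory functional
//   F = sum_i a_i * c(x(t - T_i))
// (lags pre-rounded to whole steps on the R side) and tumbles with
// probability clamp((dt/tau) * (1 - F), 0, 1).  At a tumble the direction is
// reversed with probability p_r and, if tau_t > 0, a tumble phase of
// tumble_steps steps begins.  The history is NEVER cleared at tumbles.
//
// The walker loop only accumulates per-walker sufficient statistics
// (position histogram over the sampling window, run-duration/displacement
// moments per start-position bin); full per-step and per-run records are
// optional so that test-scale runs can expose the whole trajectory.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: fast, reproducible across platforms,
// one independent stream per walker derived from the master seed.
struct Xoshiro256pp {
    uint64_t s[4];
    static uint64_t splitmix(uint64_t &x) {
        x += 0x9E3779B97F4A7C15ULL;
        uint64_t z = x;
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    explicit Xoshiro256pp(uint64_t seed) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline uint64_t next() {
        const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0];
        s[3] ^= s[1];
        s[1] ^= s[2];
        s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }
    inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

} // namespace

// [[Rcpp::export(name = ".rt_core")]]
List rt_core(IntegerVector lag_steps, NumericVector weights,
             double v, double tau, double dt, double p_r, double L,
             int tumble_steps, bool threshold,
             double c0, double c1,
             int n_walkers,
             double burn_steps_d, double sample_steps_d,
             int n_bins_hist, int n_bins_run,
             double seed_d,
             bool record_runs, bool record_steps) {
    const int n_imp = lag_steps.size();
    int max_lag = 0;
    for (int i = 0; i < n_imp; ++i)
        if (lag_steps[i] > max_lag) max_lag = lag_steps[i];
    const int H = max_lag + 1;
    const bool one_imp = (n_imp == 1);
    const int lag1 = one_imp ? lag_steps[0] : 0;
    const double w1 = one_imp ? weights[0] : 0.0;

    const long long burn_steps = (long long)burn_steps_d;
    const long long sample_steps = (long long)sample_steps_d;
    const long long total_steps = burn_steps + sample_steps;
    const double step_len = v * dt;
    const double p_base = dt / tau;
    const uint64_t master_seed = (uint64_t)seed_d;

    NumericMatrix hist(n_bins_hist, n_walkers);
    NumericMatrix run_cnt(n_bins_run, n_walkers), run_sdur(n_bins_run, n_walkers),
        run_sdur2(n_bins_run, n_walkers), run_sdisp(n_bins_run, n_walkers),
        run_sdisp2(n_bins_run, n_walkers);
    NumericVector w_nruns(n_walkers), w_sdur(n_walkers), w_sdur2(n_walkers),
        w_sdisp(n_walkers), w_sdisp2(n_walkers), w_x0(n_walkers);
    IntegerVector w_dir0(n_walkers);

    // optional full records
    std::vector<double> r_tstart, r_xstart, r_dur, r_disp;
    std::vector<int> r_walker;
    std::vector<double> s_t, s_x, s_F;
    std::vector<int> s_walker, s_dir, s_tum;
    if (record_steps) {
        s_t.reserve((size_t)(total_steps * n_walkers));
        s_x.reserve((size_t)(total_steps * n_walkers));
    }

    // the ring is stored twice so that multi-impulse lag lookups need no
    // wrap branch: entry i is mirrored at i + H, and head + H - lag is
    // always a valid index
    std::vector<double> ring(2 * (size_t)H);
    const double inv_bin_hist = n_bins_hist / L;
    const double inv_bin_run = n_bins_run / L;

    for (int w = 0; w < n_walkers; ++w) {
        // one independent stream per walker, derived from the master seed
        Xoshiro256pp rng(master_seed + (uint64_t)(w + 1) * 0x9E3779B97F4A7C15ULL);
        double *histcol = &hist(0, w);

        // start on the lattice at a uniform position, random direction
        long long n_sites = (long long)(L / step_len + 0.5);
        long long site = (long long)(rng.unif() * (double)(n_sites + 1));
        if (site > n_sites) site = n_sites;
        double x = site * step_len;
        int dir = (rng.unif() < 0.5) ? 1 : -1;
        w_x0[w] = x;
        w_dir0[w] = dir;

        const double c_fill = c0 + c1 * x;
        for (int i = 0; i < 2 * H; ++i) ring[i] = c_fill;
        int head = 0; // index of most recent entry

        int phase = 0; // remaining tumble-phase steps
        long long run_start_step = 0;
        double run_start_x = x;
        bool run_open = true;

        for (long long step = 0; step < total_steps; ++step) {
            bool tumbled = false;
            double F = 0.0;
            if (phase > 0) {
                // tumbling: no translation, history still advances
                --phase;
                ++head;
                if (head == H) head = 0;
                ring[head] = ring[head + H] = c0 + c1 * x;
                if (phase == 0) {
                    run_start_step = step + 1;
                    run_start_x = x;
                    run_open = true;
                }
            } else {
                x += dir * step_len;
                if (x > L) {
                    x = 2.0 * L - x;
                    dir = -dir;
                } else if (x < 0.0) {
                    x = -x;
                    dir = -dir;
                }
                ++head;
                if (head == H) head = 0;
                ring[head] = ring[head + H] = c0 + c1 * x;
                if (one_imp) {
                    F = w1 * ring[head + H - lag1];
                } else {
                    const int base = head + H;
                    for (int i = 0; i < n_imp; ++i)
                        F += weights[i] * ring[base - lag_steps[i]];
                }
                if (threshold && F < 0.0) F = 0.0;
                double p = p_base * (1.0 - F);
                if (p < 0.0) p = 0.0;
                else if (p > 1.0) p = 1.0;
                if (rng.unif() < p) {
                    tumbled = true;
                    // close the run
                    if (run_open && run_start_step >= burn_steps) {
                        const double dur = (double)(step - run_start_step + 1) * dt;
                        const double disp = x - run_start_x;
                        int b = (int)(run_start_x * inv_bin_run);
                        if (b >= n_bins_run) b = n_bins_run - 1;
                        run_cnt(b, w) += 1.0;
                        run_sdur(b, w) += dur;
                        run_sdur2(b, w) += dur * dur;
                        run_sdisp(b, w) += disp;
                        run_sdisp2(b, w) += disp * disp;
                        w_nruns[w] += 1.0;
                        w_sdur[w] += dur;
                        w_sdur2[w] += dur * dur;
                        w_sdisp[w] += disp;
                        w_sdisp2[w] += disp * disp;
                        if (record_runs) {
                            r_walker.push_back(w + 1);
                            r_tstart.push_back(run_start_step * dt);
                            r_xstart.push_back(run_start_x);
                            r_dur.push_back(dur);
                            r_disp.push_back(disp);
                        }
                    }
                    run_open = false;
                    if (rng.unif() < p_r) dir = -dir;
                    if (tumble_steps > 0) {
                        phase = tumble_steps;
                    } else {
                        run_start_step = step + 1;
                        run_start_x = x;
                        run_open = true;
                    }
                }
            }
            if (step >= burn_steps) {
                int b = (int)(x * inv_bin_hist);
                if (b >= n_bins_hist) b = n_bins_hist - 1;
                histcol[b] += 1.0;
            }
            if (record_steps) {
                s_walker.push_back(w + 1);
                s_t.push_back((step + 1) * dt);
                s_x.push_back(x);
                s_dir.push_back(dir);
                s_tum.push_back(tumbled ? 1 : 0);
                s_F.push_back(F);
            }
        }
    }

    List out = List::create(
        _["hist"] = hist,
        _["run_cnt"] = run_cnt, _["run_sdur"] = run_sdur,
        _["run_sdur2"] = run_sdur2, _["run_sdisp"] = run_sdisp,
        _["run_sdisp2"] = run_sdisp2,
        _["w_nruns"] = w_nruns, _["w_sdur"] = w_sdur, _["w_sdur2"] = w_sdur2,
        _["w_sdisp"] = w_sdisp, _["w_sdisp2"] = w_sdisp2,
        _["x0"] = w_x0, _["dir0"] = w_dir0);
    if (record_runs) {
        out["runs"] = DataFrame::create(
            _["walker"] = r_walker, _["t_start"] = r_tstart,
            _["x_start"] = r_xstart, _["duration_s"] = r_dur,
            _["displacement_um"] = r_disp);
    }
    if (record_steps) {
        out["steps"] = DataFrame::create(
            _["walker"] = s_walker, _["t"] = s_t, _["x"] = s_x,
            _["dir"] = s_dir, _["tumbled"] = s_tum, _["F"] = s_F);
    }
    return out;
}
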