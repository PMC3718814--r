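#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Tabular SARSA(lambda) training loop on the rake-and-pellet gridworld.
// The environment dynamics are inlined for speed; they mirror rake_step()
// exactly (the R test suite replays logged transitions through the R-level
// update to verify agreement). Uses R's RNG so runs are reproducible from
// set.seed().

static inline int state_index(int pd, int dx, int dy) {
  return (pd - 1) * 169 + (dx + 6) * 13 + (dy + 6);  // 0-based
}

// [[Rcpp::export]]
List sarsa_train_cpp(int n_steps, double epsilon, double lambda,
                     double gamma, double alpha0, bool replacing,
                     double q_init, double accuracy, double reward_success,
                     double reward_failure, double step_penalty,
                     int start_dx, int start_dy, int step_cap,
                     bool log_transitions) {
  const int NS = 1183, NA = 4;
  std::vector<double> Q(NS * NA, q_init), E(NS * NA, 0.0);
  std::vector<int> visits(NS * NA, 0);
  std::vector<int> active;  // indices with nonzero eligibility trace
  active.reserve(4096);

  std::vector<int> ep_steps;
  std::vector<int> ep_success, ep_trunc;
  std::vector<double> ep_true_r, ep_deliv_r;
  std::vector<int> tr_s, tr_a, tr_s2, tr_a2, tr_term, tr_reset;
  std::vector<double> tr_r;

  RNGScope scope;

  auto pick_action = [&](int s) -> int {
    double best = Q[s * NA];
    for (int k = 1; k < NA; ++k) if (Q[s * NA + k] > best) best = Q[s * NA + k];
    int ties[4], nt = 0, others[4], no = 0;
    for (int k = 0; k < NA; ++k) {
      if (Q[s * NA + k] == best) ties[nt++] = k; else others[no++] = k;
    }
    if (unif_rand() >= epsilon) {
      return nt == 1 ? ties[0] : ties[(int)(unif_rand() * nt) % nt];
    }
    if (no == 0) return ties[(int)(unif_rand() * nt) % nt];
    return others[(int)(unif_rand() * no) % no];
  };

  auto clear_traces = [&]() {
    for (int idx : active) E[idx] = 0.0;
    active.clear();
  };

  // Each traced pair updates with its own annealed rate
  // alpha0 / (1 + visits); the visit count of (s, a) increments after the
  // update so a pair's first update uses alpha0.
  auto update = [&](int s, int a, double r, int s2, int a2, bool terminal) {
    int sa = s * NA + a;
    double target = terminal ? 0.0 : Q[s2 * NA + a2];
    double delta = r + gamma * target - Q[sa];
    if (E[sa] == 0.0) active.push_back(sa);
    E[sa] = replacing ? 1.0 : E[sa] + 1.0;
    double gl = gamma * lambda;
    size_t w = 0;
    for (size_t i = 0; i < active.size(); ++i) {
      int idx = active[i];
      Q[idx] += alpha0 / (1.0 + visits[idx]) * delta * E[idx];
      E[idx] *= gl;
      if (E[idx] > 1e-12) active[w++] = idx; else E[idx] = 0.0;
    }
    active.resize(w);
    visits[sa] += 1;
  };

  int pd = 4, dx = start_dx, dy = start_dy;
  int s = state_index(pd, dx, dy);
  int a = pick_action(s);
  int steps_in_ep = 0;

  for (int step = 0; step < n_steps; ++step) {
    // environment transition
    double r = step_penalty;
    bool terminal = false;
    double true_r = 0.0;
    int pd2 = pd, dx2 = dx, dy2 = dy;
    if (a <= 1) {                       // 0 = left, 1 = right
      int nx = dx + (a == 0 ? -1 : 1);
      if (nx >= -6 && nx <= 6) dx2 = nx;
    } else {
      int d = (a == 2) ? -1 : 1;        // 2 = pull, 3 = push
      if (dx >= -1 && dx <= 1 && dy + d == 0) {
        pd2 = pd + d;
        if (pd2 < 1) { terminal = true; true_r = reward_success; }
        else if (pd2 > 7) { terminal = true; true_r = reward_failure; }
      } else {
        int ny = dy + d;
        if (ny >= -6 && ny <= 6) dy2 = ny;
      }
    }
    steps_in_ep += 1;

    if (terminal) {
      bool success = (true_r == reward_success);
      bool correct = (unif_rand() < accuracy);
      double other = success ? reward_failure : reward_success;
      double delivered = correct ? true_r : other;
      update(s, a, delivered, 0, 0, true);
      if (log_transitions) {
        tr_s.push_back(s + 1); tr_a.push_back(a + 1);
        tr_r.push_back(delivered); tr_s2.push_back(0); tr_a2.push_back(0);
        tr_term.push_back(1); tr_reset.push_back(1);
      }
      ep_steps.push_back(steps_in_ep);
      ep_success.push_back(success ? 1 : 0);
      ep_true_r.push_back(true_r);
      ep_deliv_r.push_back(delivered);
      ep_trunc.push_back(0);
      pd = 4; dx = start_dx; dy = start_dy;
      s = state_index(pd, dx, dy);
      a = pick_action(s);
      steps_in_ep = 0;
      clear_traces();
      continue;
    }

    int s2 = state_index(pd2, dx2, dy2);
    int a2 = pick_action(s2);
    update(s, a, r, s2, a2, false);
    if (log_transitions) {
      tr_s.push_back(s + 1); tr_a.push_back(a + 1);
      tr_r.push_back(r); tr_s2.push_back(s2 + 1); tr_a2.push_back(a2 + 1);
      tr_term.push_back(0);
    }

    if (steps_in_ep >= step_cap) {      // truncated: no terminal reward
      ep_steps.push_back(steps_in_ep);
      ep_success.push_back(0);
      ep_true_r.push_back(0.0);
      ep_deliv_r.push_back(0.0);
      ep_trunc.push_back(1);
      if (log_transitions) tr_reset.push_back(1);
      pd = 4; dx = start_dx; dy = start_dy;
      s = state_index(pd, dx, dy);
      a = pick_action(s);
      steps_in_ep = 0;
      clear_traces();
    } else {
      if (log_transitions) tr_reset.push_back(0);
      pd = pd2; dx = dx2; dy = dy2;
      s = s2; a = a2;
    }
  }

  NumericMatrix Qm(NS, NA);
  IntegerMatrix Vm(NS, NA);
  for (int i = 0; i < NS; ++i)
    for (int k = 0; k < NA; ++k) {
      Qm(i, k) = Q[i * NA + k];
      Vm(i, k) = visits[i * NA + k];
    }

  List out = List::create(
    _["Q"] = Qm, _["visits"] = Vm,
    _["steps"] = wrap(ep_steps),
    _["true_success"] = LogicalVector(ep_success.begin(), ep_success.end()),
    _["true_reward"] = wrap(ep_true_r),
    _["delivered_reward"] = wrap(ep_deliv_r),
    _["truncated"] = LogicalVector(ep_trunc.begin(), ep_trunc.end()));
  if (log_transitions) {
    out["tr_s"] = wrap(tr_s); out["tr_a"] = wrap(tr_a);
    out["tr_r"] = wrap(tr_r); out["tr_s2"] = wrap(tr_s2);
    out["tr_a2"] = wrap(tr_a2);
    out["tr_terminal"] = LogicalVector(tr_term.begin(), tr_term.end());
    out["tr_reset"] = LogicalVector(tr_reset.begin(), tr_reset.end());
  }
  return out;
}
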