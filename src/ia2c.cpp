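// Independent advantage actor-critic (IA2C) pretraining for the
// route-choice game. Each agent owns a small actor network (softmax over
// {local, expressway}) and a critic, trained online with one-step TD
// advantage while all agents play the shared congestion environment.
// Deployment (frozen greedy action selection) happens on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

constexpr int N_FEAT = 7;

struct Adam {
  mat m, v;
  long t = 0;
  Adam(int r, int c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  // in-place gradient-ascent step
  void step(mat &w, const mat &g, double lr) {
    ++t;
    const double mc = 1.0 - std::pow(0.9, (double)t);
    const double vc = 1.0 - std::pow(0.999, (double)t);
    const double vcr = 1.0 / std::sqrt(vc);
    double *wp = w.memptr(), *mp = m.memptr(), *vp = v.memptr();
    const double *gp = g.memptr();
    const uword n = w.n_elem;
    for (uword j = 0; j < n; ++j) {
      mp[j] = 0.9 * mp[j] + 0.1 * gp[j];
      vp[j] = 0.999 * vp[j] + 0.001 * gp[j] * gp[j];
      wp[j] += lr * (mp[j] / mc) / (std::sqrt(vp[j]) * vcr + 1e-8);
    }
  }
};

// two-hidden-layer perceptron head (tanh) with its Adam state
struct Mlp {
  mat W1, b1, W2, b2, W3, b3;
  Adam aW1, ab1, aW2, ab2, aW3, ab3;
  Mlp(int h, int n_out, std::mt19937 &gen)
      : W1(h, N_FEAT), b1(h, 1, fill::zeros), W2(h, h),
        b2(h, 1, fill::zeros), W3(n_out, h), b3(n_out, 1, fill::zeros),
        aW1(h, N_FEAT), ab1(h, 1), aW2(h, h), ab2(h, 1), aW3(n_out, h),
        ab3(n_out, 1) {
    std::normal_distribution<double> nd(0.0, 1.0);
    auto init = [&](mat &w, double sd) {
      for (uword i = 0; i < w.n_elem; ++i) w(i) = sd * nd(gen);
    };
    init(W1, 1.0 / std::sqrt((double)N_FEAT));
    init(W2, 1.0 / std::sqrt((double)h));
    init(W3, 1.0 / std::sqrt((double)h));
  }
  vec forward(const vec &f, vec &h1, vec &h2) const {
    h1 = tanh(W1 * f + b1.col(0));
    h2 = tanh(W2 * h1 + b2.col(0));
    return W3 * h2 + b3.col(0);
  }
  // backpropagate d(objective)/d(output) and take an ascent step
  void ascend(const vec &f, const vec &h1, const vec &h2, const vec &gout,
              double lr) {
    mat gW3 = gout * h2.t();
    vec dh2 = (W3.t() * gout) % (1.0 - h2 % h2);
    mat gW2 = dh2 * h1.t();
    vec dh1 = (W2.t() * dh2) % (1.0 - h1 % h1);
    mat gW1 = dh1 * f.t();
    aW3.step(W3, gW3, lr);
    ab3.step(b3, mat(gout), lr);
    aW2.step(W2, gW2, lr);
    ab2.step(b2, mat(dh2), lr);
    aW1.step(W1, gW1, lr);
    ab1.step(b1, mat(dh1), lr);
  }
};

struct Net {
  Mlp actor, critic;
  Net(int h, std::mt19937 &gen) : actor(h, 2, gen), critic(h, 1, gen) {}
  vec actor_probs(const vec &f, vec &h1, vec &h2) const {
    vec z = actor.forward(f, h1, h2);
    z -= z.max();
    vec p = exp(z);
    return p / accu(p);
  }
  double critic_value(const vec &f, vec &h1, vec &h2) const {
    return as_scalar(critic.forward(f, h1, h2));
  }
};

struct Bpr {
  double a, alpha, s, beta;
  double cost(int n) const {
    return a * (1.0 + alpha * std::pow((double)n / s, beta));
  }
};

} // namespace

// Train one roster of independent actor-critic agents by self-play.
//
// routes: list of 3 lists (a, alpha, s, beta) ordered Local1, Expressway,
//         Local2; od: integer vector (1 or 2) per agent; local_idx maps an
//         agent to its local route (0-based into routes).
// [[Rcpp::export]]
Rcpp::List ia2c_train(Rcpp::List routes, Rcpp::IntegerVector od,
                      int episodes, int steps_per_episode, double lr,
                      double discount, double entropy_coef, int hidden,
                      double reward_scale, double lr_decay_to,
                      double entropy_anneal_frac, int seed) {
  const int n_agents = od.size();
  std::vector<Bpr> bpr(3);
  for (int j = 0; j < 3; ++j) {
    Rcpp::List r = routes[j];
    bpr[j] = {Rcpp::as<double>(r["a"]), Rcpp::as<double>(r["alpha"]),
              Rcpp::as<double>(r["s"]), Rcpp::as<double>(r["beta"])};
  }
  std::vector<int> local_idx(n_agents);
  vec demand(2, fill::zeros);
  for (int i = 0; i < n_agents; ++i) {
    local_idx[i] = (od[i] == 1) ? 0 : 2;
    demand(od[i] - 1) += 1.0;
  }
  const double d_total = n_agents;

  std::mt19937 gen(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<Net> nets;
  nets.reserve(n_agents);
  for (int i = 0; i < n_agents; ++i) nets.emplace_back(hidden, gen);

  const int T = steps_per_episode;
  vec history(std::max(episodes, 1), fill::zeros);

  // previous-interval state
  std::vector<int> prev_route(n_agents); // 0,1,2 ; -1 = none
  vec prev_cost(3, fill::zeros);
  ivec prev_count(3, fill::zeros);

  auto features = [&](int i, int t) {
    vec f(N_FEAT, fill::zeros);
    if (t > 1) {
      const int li = local_idx[i];
      f(0) = (double)prev_count(li) / demand(od[i] - 1);
      f(1) = (double)prev_count(1) / d_total;
      f(2) = prev_cost(li) / bpr[li].a;
      f(3) = prev_cost(1) / bpr[1].a;
      f(4) = prev_route[i] == li ? 1.0 : 0.0;
      f(5) = prev_route[i] == 1 ? 1.0 : 0.0;
    }
    f(6) = (double)(t - 1) / (double)T;
    return f;
  };

  // one cached forward pass per agent-step; gradients are evaluated at the
  // action-time activations (the probabilities the action was sampled from)
  struct Cache {
    vec f, p, ha1, ha2, hc1, hc2;
    double V = 0.0;
    int a = 0;
    double r = 0.0;
  };

  auto update = [&](Net &net, const Cache &c, double Vp, bool done,
                    double lr_t, double ent_t) {
    const double delta = c.r + (done ? 0.0 : discount * Vp) - c.V;
    // critic: ascend -0.5 * delta^2  =>  d(obj)/dV = delta
    vec gout(1);
    gout(0) = delta;
    net.critic.ascend(c.f, c.hc1, c.hc2, gout, lr_t);
    // actor: ascend delta * log pi(a|s) + ent * H(pi)
    vec gz = -delta * c.p;
    gz(c.a) += delta;
    vec logp = log(c.p + 1e-12);
    const double H = -dot(c.p, logp);
    gz += ent_t * (-c.p % (logp + H));
    net.actor.ascend(c.f, c.ha1, c.ha2, gz, lr_t);
  };

  std::vector<Cache> prev(n_agents), cur(n_agents);

  for (int ep = 0; ep < episodes; ++ep) {
    const double frac = episodes > 1 ? (double)ep / (double)(episodes - 1)
                                     : 0.0;
    const double lr_t = lr * (1.0 - (1.0 - lr_decay_to) * frac);
    const double ent_t =
        entropy_coef *
        std::max(0.0, 1.0 - frac / std::max(entropy_anneal_frac, 1e-9));

    std::fill(prev_route.begin(), prev_route.end(), -1);
    prev_cost.zeros();
    prev_count.zeros();
    double ep_cost = 0.0;

    for (int t = 1; t <= T; ++t) {
      ivec count(3, fill::zeros);
      std::vector<int> choice(n_agents);
      for (int i = 0; i < n_agents; ++i) {
        Cache &c = cur[i];
        c.f = features(i, t);
        c.p = nets[i].actor_probs(c.f, c.ha1, c.ha2);
        c.V = nets[i].critic_value(c.f, c.hc1, c.hc2);
        // bootstrap the pending transition with the fresh state value
        if (t > 1) update(nets[i], prev[i], c.V, false, lr_t, ent_t);
        c.a = (unif(gen) < c.p(0)) ? 0 : 1; // 0 = local, 1 = expressway
        choice[i] = (c.a == 0) ? local_idx[i] : 1;
        ++count(choice[i]);
      }
      vec cost(3);
      for (int j = 0; j < 3; ++j) cost(j) = bpr[j].cost(count(j));
      for (int i = 0; i < n_agents; ++i) {
        const double c = cost(choice[i]);
        cur[i].r = -c * reward_scale;
        ep_cost += c;
      }
      std::swap(prev, cur);
      for (int i = 0; i < n_agents; ++i) prev_route[i] = choice[i];
      prev_cost = cost;
      prev_count = count;
    }
    for (int i = 0; i < n_agents; ++i)
      update(nets[i], prev[i], 0.0, true, lr_t, ent_t);
    history(ep) = ep_cost / T; // mean per-interval system travel time
    if (!std::isfinite(history(ep)) || !nets[0].actor.W1.is_finite())
      Rcpp::stop("IA2C training diverged (non-finite values) at episode %d",
                 ep + 1);
    if (ep % 64 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List pol(n_agents);
  for (int i = 0; i < n_agents; ++i)
    pol[i] = Rcpp::List::create(
        Rcpp::Named("W1") = nets[i].actor.W1,
        Rcpp::Named("b1") = nets[i].actor.b1,
        Rcpp::Named("W2") = nets[i].actor.W2,
        Rcpp::Named("b2") = nets[i].actor.b2,
        Rcpp::Named("W3") = nets[i].actor.W3,
        Rcpp::Named("b3") = nets[i].actor.b3,
        Rcpp::Named("od") = od[i]);
  return Rcpp::List::create(
      Rcpp::Named("policies") = pol,
      Rcpp::Named("history") =
          episodes > 0 ? Rcpp::NumericVector(history.begin(), history.end())
                       : Rcpp::NumericVector(0));
}
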