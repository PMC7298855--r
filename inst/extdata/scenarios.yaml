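typical:
  researchers: university_health
  data_type: primary_care_other_health
  purpose: public_benefits
  profit: invested_public_services
  oversight: relevant_public_service
best_case:
  researchers: university_only
  data_type: primary_care_other_health
  purpose: direct_benefits
  profit: nobody_profits
  oversight: independent_body
worst_case:
  researchers: university_health_gov_commercial
  data_type: health_all_incl_private_sector
  purpose: any_reason
  profit: kept_by_researchers
  oversight: research_organisation
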