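researchers:
  levels:
  - university_only
  - university_health
  - university_health_gov
  - university_health_gov_commercial
  base: university_health_gov_commercial
data_type:
  levels:
  - primary_care_other_health
  - health_social_education
  - health_social_edu_emp_benefits
  - health_all_incl_private_sector
  base: health_all_incl_private_sector
purpose:
  levels:
  - direct_benefits
  - public_benefits
  - any_reason
  base: any_reason
profit:
  levels:
  - nobody_profits
  - shared_with_public
  - invested_public_services
  - kept_by_researchers
  base: kept_by_researchers
oversight:
  levels:
  - government
  - independent_body
  - relevant_public_service
  - research_organisation
  base: research_organisation
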