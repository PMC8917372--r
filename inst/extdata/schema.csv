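column,type,allowed
household_id,integer,positive
person_id,integer,positive
year,integer,2005-2019
quarter,integer,1|2|3|4
visit_number,integer,1|2|3|4|5
stratum_id,integer,positive
psu_id,integer,positive
weight,double,"> 0 (expansion factor, persons represented)"
occupation_code,string,occupation catalogue code; nurse codes supplied via config
economically_active,logical,TRUE|FALSE
working,logical,TRUE|FALSE
available_and_seeking,logical,TRUE|FALSE
sector,string,public|private|none (none iff not working)
in_health_sector,logical,TRUE|FALSE (FALSE if not working)
weekly_hours,double,">= 0; NA if not working or item nonresponse"
income_mw,double,">= 0, income as multiple of the minimum wage; NA if not working or item nonresponse"
written_contract,logical,TRUE|FALSE; NA if not working or item nonresponse
any_social_benefit,logical,TRUE|FALSE; NA if not working or item nonresponse
ss_health_access,logical,TRUE|FALSE; NA if not working or item nonresponse
sex,string,female|male
age_band,string,<=24|25-54|>=55
marital,string,married_union|single|div_widowed
university,logical,TRUE|FALSE (bachelor's or other university degree)
n_jobs,string,1|>=2
residence,string,rural|semi_urban|urban|metropolitan
region,integer,1 (poorest) - 6 (wealthiest) socioeconomic region
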